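#' Procrustes linear model: variance partitioned over model terms
#'
#' Multivariate linear model on flattened shape (or form) variables with
#' sequential (order-of-entry) sums of squares summed across all coordinates,
#' so each term receives a fraction of the total shape variance. Significance
#' is assessed by residual-randomization permutation (Freedman–Lane): for
#' each term the residuals of the model containing the preceding terms are
#' permuted, the pseudo-F recomputed, and the p-value taken as the proportion
#' of permuted statistics at least as large as the observed one, with +1
#' smoothing so p is never exactly zero.
#'
#' @param shape_vars Numeric matrix, specimens x variables (e.g.
#'   [shape_matrix()] or [form_matrix()] output).
#' @param data Data frame of predictors, one row per specimen.
#' @param formula Right-hand-side formula over columns of `data`; terms enter
#'   the decomposition in formula order (default `~ size + sex + size:sex`,
#'   mirroring a size-then-sex-then-interaction decomposition).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `procrustes_lm` tibble: one row per term plus a residual row,
#'   with columns `term`, `df`, `ss`, `fraction`, `statistic`, `p_value`.
#'   Fractions (terms plus residual) sum to 1.
#' @export
procrustes_lm <- function(shape_vars, data, formula = ~ size + sex + size:sex,
                          n_perm = 999L, seed = 1L) {
  y <- as.matrix(shape_vars)
  if (nrow(y) != nrow(data)) abort("shape_vars and data must have the same rows")
  trm <- stats::terms(formula, data = data)
  mm <- stats::model.matrix(trm, data = data)
  assign <- attr(mm, "assign")
  labels <- attr(trm, "term.labels")
  n_terms <- length(labels)
  n <- nrow(y)
  if (n < n_terms + 2) abort("too few specimens for the requested terms")
  if (qr(mm)$rank < ncol(mm)) {
    abort(paste0("confounded (rank-deficient) model terms: ",
                 paste(labels, collapse = ", ")))
  }

  yc <- sweep(y, 2, colMeans(y))
  ss_total <- sum(yc^2)
  if (ss_total < 1e-300) abort("shape variables have zero variance")

  # orthonormal bases of the nested models (intercept-first ordering)
  qs <- vector("list", n_terms)
  dfs <- integer(n_terms)
  for (j in seq_len(n_terms)) {
    xj <- mm[, assign <= j, drop = FALSE]
    qs[[j]] <- qr.Q(qr(xj))[, seq_len(qr(xj)$rank), drop = FALSE]
    dfs[j] <- sum(assign == j)
  }

  seq_ss <- function(ymat) {
    out <- numeric(n_terms)
    prev <- sum(sweep(ymat, 2, colMeans(ymat))^2)  # after intercept only
    tot0 <- prev
    for (j in seq_len(n_terms)) {
      fitted_ss <- sum((crossprod(qs[[j]], ymat))^2)
      # fitted SS includes the intercept projection; convert to residual SS
      rss <- sum(ymat^2) - fitted_ss
      out[j] <- prev - rss
      prev <- rss
    }
    list(ss = out, rss = prev, total = tot0)
  }

  obs <- seq_ss(y)
  df_res <- n - 1 - sum(dfs)
  # guard saturated (zero-residual) fits: 0/0 pseudo-F means nothing left to
  # explain -> statistic 0; positive SS over zero residual -> +Inf
  tiny <- 1e-300
  f_obs <- (obs$ss / dfs) / ((obs$rss + tiny) / df_res)

  exceed <- rep(0L, n_terms)
  for (t in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 7L, t))
    perm <- sample.int(n)
    for (j in seq_len(n_terms)) {
      # Freedman-Lane: permute residuals of the reduced model (terms < j)
      if (j == 1) {
        fit_red <- rep(colMeans(y), each = n)
        res_red <- yc
      } else {
        proj <- qs[[j - 1]] %*% crossprod(qs[[j - 1]], y)
        fit_red <- proj
        res_red <- y - proj
      }
      ystar <- fit_red + res_red[perm, , drop = FALSE]
      st <- seq_ss(ystar)
      f_star <- (st$ss[j] / dfs[j]) / ((st$rss + tiny) / df_res)
      if (f_star >= f_obs[j] - 1e-12) exceed[j] <- exceed[j] + 1L
    }
  }
  p <- (exceed + 1) / (n_perm + 1)

  out <- tibble(
    term = c(labels, "residual"),
    df = c(dfs, df_res),
    ss = c(obs$ss, obs$rss),
    fraction = c(obs$ss, obs$rss) / obs$total,
    statistic = c(f_obs, NA_real_),
    p_value = c(p, NA_real_)
  )
  class(out) <- c("procrustes_lm", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' @export
glance.procrustes_lm <- function(x, ...) {
  tibble(n_terms = nrow(x) - 1, n_perm = attr(x, "n_perm"),
         residual_fraction = x$fraction[nrow(x)])
}

#' Digitization repeatability by Procrustes ANOVA
#'
#' Quantifies measurement error from a balanced replicated-digitization
#' design: all digitizations are superimposed jointly by GPA, then a one-way
#' ANOVA across individuals is computed on the aligned coordinates with sums
#' of squares pooled over all coordinates. Repeatability is the intraclass
#' proportion of variance among individuals,
#' `R = (MS_among - MS_within) / (MS_among + (r - 1) MS_within)`,
#' reported as a percentage clamped to \[0, 100\].
#'
#' @param x A `specimen_set` containing `r` digitizations of each individual
#'   (replicates linked by `replicate_of`, or supply `individuals`), or a
#'   numeric matrix of already-aligned shape variables.
#' @param individuals Vector of individual ids, one per specimen/row.
#'   Defaults to `replicate_of` (falling back to `specimen_id`) for a
#'   `specimen_set`.
#' @return A one-row tibble with `repeatability` (percent), `ms_among`,
#'   `ms_within`, `n_individuals`, `n_replicates`.
#' @export
repeatability <- function(x, individuals = NULL) {
  if (inherits(x, "specimen_set")) {
    if (is.null(individuals)) {
      sp <- x$specimens
      individuals <- ifelse(is.na(sp$replicate_of), sp$specimen_id, sp$replicate_of)
    }
    fit <- gpa(x, scale = TRUE)
    y <- flatten_configs(fit$aligned)
  } else {
    y <- as.matrix(x)
    if (is.null(individuals)) abort("individuals must be given for a matrix input")
  }
  individuals <- as.character(individuals)
  counts <- table(individuals)
  r <- unique(as.integer(counts))
  if (length(r) != 1) abort("unbalanced design: all individuals need the same replicate count")
  if (r < 2) abort("repeatability needs at least 2 replicates per individual")
  a <- length(counts)
  grand <- colMeans(y)
  ss_within <- 0; ss_among <- 0
  for (id in names(counts)) {
    rows <- y[individuals == id, , drop = FALSE]
    m <- colMeans(rows)
    ss_within <- ss_within + sum(sweep(rows, 2, m)^2)
    ss_among <- ss_among + r * sum((m - grand)^2)
  }
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (a * (r - 1))
  rep_pct <- 100 * (ms_among - ms_within) / (ms_among + (r - 1) * ms_within)
  tibble(
    repeatability = min(100, max(0, rep_pct)),
    ms_among = ms_among, ms_within = ms_within,
    n_individuals = a, n_replicates = r
  )
}
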