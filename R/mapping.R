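#' Per-point neighborhoods on a consensus shape
#'
#' Defines, for every landmark/semilandmark, the local patch analysed by
#' [map_signal()]: the point itself plus its `k - 1` nearest neighbors by
#' Euclidean distance on the consensus configuration (ties broken toward the
#' lower point index). Neighborhoods are computed once, from the consensus,
#' so every permutation of the mapping shares the same spatial support.
#'
#' @param consensus `n_points x 3` matrix, usually `gpa(x)$consensus`.
#' @param k Neighborhood size, counting the focal point (default 10). Set
#'   `k_excludes_focal = TRUE` to read `k` as the number of neighbors
#'   around the focal point instead.
#' @param k_excludes_focal See `k`.
#' @return A `neighborhoods` object: tibble `(focal, members)` with a
#'   list-column of integer index vectors, one row per point.
#' @export
build_neighborhoods <- function(consensus, k = 10L, k_excludes_focal = FALSE) {
  consensus <- as.matrix(consensus)
  n <- nrow(consensus)
  size <- if (k_excludes_focal) k + 1L else as.integer(k)
  if (size < 4) abort("neighborhood size below 4: a local Procrustes fit needs >= 4 points")
  if (size > n) abort("k exceeds the number of points")
  d <- as.matrix(stats::dist(consensus))
  members <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))  # stable: ties to the lower index
    as.integer(ord[seq_len(size)])   # self has distance 0, always first
  })
  out <- tibble(focal = seq_len(n), members = members)
  class(out) <- c("neighborhoods", class(out))
  attr(out, "k") <- size
  attr(out, "consensus") <- consensus
  out
}

# symmetric adjacency: i ~ j if either is in the other's neighborhood
neighborhood_graph <- function(nb) {
  n <- nrow(nb)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, setdiff(nb$members[[i]], i))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(igraph::add_vertices(g, max(0, n - igraph::vcount(g))))
}

#' Map a binary signal onto every point of a landmark configuration
#'
#' The core local-classification pipeline: for each point's neighborhood and
#' each permutation, specimens are split into stratified training (70% per
#' class by default) and test sets; a fresh GPA (with scaling) is run on the
#' training subconfigurations alone; features are built in the requested
#' space (`"shape"`: flattened aligned coordinates; `"form"`: those plus the
#' log centroid size of the neighborhood; `"size"`: the log neighborhood
#' centroid size alone); test specimens are projected into the training
#' frame by ordinary Procrustes superimposition (never included in the
#' training GPA); a PCA fitted on the training features is truncated at the
#' cumulative variance threshold (shape/form only); and a two-class LDA is
#' fitted and scored on the held-out specimens. The map value at a point is
#' the mean accuracy over permutations, reported overall and per class.
#'
#' A full map runs `n_points * n_perm` independent discriminant analyses
#' (the reference configuration of 1050 points at 100 permutations implies
#' 105,000).
#'
#' @param x A `specimen_set` with complete F/M labels.
#' @param space `"shape"`, `"form"` or `"size"`.
#' @param k Neighborhood size including the focal point (default 10).
#' @param n_perm Random splits per point (default 100).
#' @param train_fraction Training fraction per class (default 0.7).
#' @param variance_threshold Cumulative variance retained by the training
#'   PCA (default 0.9).
#' @param seed Integer seed. Per-(point, permutation) RNG streams are derived
#'   from it, so maps are reproducible and independent of evaluation order.
#' @param k_excludes_focal Passed to [build_neighborhoods()].
#' @param priors LDA priors (see [lda_accuracy()]).
#' @return An `accuracy_map`: tibble `(point_id, acc_total, acc_f, acc_m,
#'   n_perm_ok)` with the run parameters, consensus coordinates and
#'   neighborhoods stored as attributes. Points whose local fit failed in
#'   more than half the permutations carry `NA`.
#' @export
map_signal <- function(x, space = c("shape", "form", "size"), k = 10L,
                       n_perm = 100L, train_fraction = 0.7,
                       variance_threshold = 0.9, seed = 1L,
                       k_excludes_focal = FALSE,
                       priors = c("proportional", "equal")) {
  space <- match.arg(space)
  priors <- match.arg(priors)
  stopifnot(inherits(x, "specimen_set"))
  labels <- as_fm_factor(check_sex_labels(x))
  if (any(table(labels) < 4)) abort("both classes need at least 4 specimens")

  full <- gpa(x, scale = TRUE)
  nb <- build_neighborhoods(full$consensus, k, k_excludes_focal)
  arr <- x$array
  ids <- dimnames(arr)[[3]]
  n_pts <- dim(arr)[1]

  res <- lapply(seq_len(n_pts), function(p) {
    map_one_point(arr, labels, ids, nb$members[[p]], space, n_perm,
                  train_fraction, variance_threshold, seed, p, priors)
  })
  acc <- do.call(rbind, lapply(res, `[[`, "acc"))
  out <- tibble(
    point_id = dimnames(arr)[[1]],
    acc_total = acc[, 1], acc_f = acc[, 2], acc_m = acc[, 3],
    n_perm_ok = vapply(res, `[[`, integer(1), "n_ok")
  )
  class(out) <- c("accuracy_map", class(out))
  attr(out, "space") <- space
  attr(out, "k") <- attr(nb, "k")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "train_fraction") <- train_fraction
  attr(out, "variance_threshold") <- variance_threshold
  attr(out, "consensus") <- full$consensus
  attr(out, "neighborhoods") <- nb
  attr(out, "n_test") <- test_counts(labels, train_fraction)
  out
}

check_sex_labels <- function(x) {
  sx <- x$specimens$sex
  if (anyNA(sx)) {
    abort(paste0("missing sex label for specimen(s): ",
                 paste(x$specimens$specimen_id[is.na(sx)], collapse = ", ")))
  }
  sx
}

test_counts <- function(labels, train_fraction) {
  tab <- table(labels)
  n_tr <- floor(tab * train_fraction + 1e-9)
  as.integer(tab - n_tr)
}

# one neighborhood: n_perm local GPA + PCA + LDA rounds
map_one_point <- function(arr, labels, ids, members, space, n_perm,
                          train_fraction, variance_threshold, seed, p, priors) {
  sub <- arr[members, , , drop = FALSE]
  k <- length(members)
  log_cs <- if (space != "shape") log(cpp_subset_csize(arr, members - 1L)) else NULL
  acc <- matrix(NA_real_, n_perm, 3)
  for (t in seq_len(n_perm)) {
    set.seed(derive_seed(seed, p, t))
    sp <- tryCatch(stratified_split(ids, labels, train_fraction),
                   error = function(e) NULL)
    if (is.null(sp)) next
    ok <- tryCatch({
      if (space == "size") {
        xtr <- matrix(log_cs[sp$train], ncol = 1)
        xte <- matrix(log_cs[sp$test], ncol = 1)
      } else {
        fit <- cpp_gpa(sub[, , sp$train, drop = FALSE], TRUE, 1e-9, 100L)
        proj <- cpp_project_to_consensus(sub[, , sp$test, drop = FALSE],
                                         fit$consensus, TRUE)
        xtr <- flatten_configs(fit$aligned)
        xte <- flatten_configs(proj$aligned)
        if (space == "form") {
          xtr <- cbind(xtr, log_cs[sp$train])
          xte <- cbind(xte, log_cs[sp$test])
        }
        pr <- pca_truncate(xtr, xte, variance_threshold)
        xtr <- pr$train; xte <- pr$test
      }
      fit2 <- fit_lda2(xtr, labels[sp$train], priors)
      acc[t, ] <- accuracy_by_class(labels[sp$test], predict_lda2(fit2, xte))
      TRUE
    }, error = function(e) FALSE)
  }
  done <- !is.na(acc[, 1])
  n_ok <- sum(done)
  if (n_ok <= n_perm / 2) {
    return(list(acc = rep(NA_real_, 3), n_ok = as.integer(n_ok), per_perm = acc))
  }
  list(acc = colMeans(acc[done, , drop = FALSE]), n_ok = as.integer(n_ok),
       per_perm = acc)
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat("<accuracy_map> space=", attr(x, "space"), " k=", attr(x, "k"),
      " n_perm=", attr(x, "n_perm"), " seed=", attr(x, "seed"), "\n", sep = "")
  cat("  acc_total: min ", round(min(x$acc_total, na.rm = TRUE), 3),
      ", max ", round(max(x$acc_total, na.rm = TRUE), 3),
      " at ", x$point_id[which.max(x$acc_total)], "\n", sep = "")
  NextMethod()
}

#' Classification accuracy of a set of combined modules
#'
#' Applies the [map_signal()] pipeline (stratified split, training-only GPA,
#' space-specific features, PCA truncation, LDA) once to the union of the
#' given point-index sets instead of per-point neighborhoods — used to score
#' candidate anatomical modules, alone or combined, typically at a higher
#' permutation count (default 1000).
#'
#' @param x A `specimen_set` with complete F/M labels.
#' @param modules A list of integer point-index vectors (or a single vector);
#'   their union defines the analysed configuration.
#' @inheritParams map_signal
#' @return An `accuracy_result` (see [lda_accuracy()]).
#' @export
combined_module_accuracy <- function(x, modules, space = c("shape", "form", "size"),
                                     n_perm = 1000L, train_fraction = 0.7,
                                     variance_threshold = 0.9, seed = 1L,
                                     priors = c("proportional", "equal")) {
  space <- match.arg(space)
  priors <- match.arg(priors)
  stopifnot(inherits(x, "specimen_set"))
  labels <- as_fm_factor(check_sex_labels(x))
  if (!is.list(modules)) modules <- list(modules)
  members <- sort(unique(unlist(modules)))
  if (length(members) == 0) abort("empty module union")
  if (any(members < 1 | members > dim(x$array)[1])) abort("module indices out of range")
  ids <- dimnames(x$array)[[3]]
  res <- map_one_point(x$array, labels, ids, as.integer(members), space, n_perm,
                       train_fraction, variance_threshold, seed, 0L, priors)
  acc <- res$per_perm
  acc <- acc[!is.na(acc[, 1]), , drop = FALSE]
  if (nrow(acc) == 0) abort("all permutations failed for the requested modules")
  new_accuracy_result(acc, labels, nrow(acc), train_fraction,
                      variance_threshold, seed)
}

#' Extract high-accuracy modules from an accuracy map
#'
#' Reproducible surrogate for picking anatomical regions off a map by eye:
#' selects the points at or above a cutoff and partitions them into connected
#' components of the neighborhood graph (two points are connected when either
#' belongs to the other's neighborhood), sorted by their peak accuracy.
#'
#' @param map An `accuracy_map`.
#' @param cutoff Absolute accuracy cutoff; or
#' @param top_quantile Quantile of the map's `acc_total` to use as the cutoff
#'   (e.g. 0.75 for the third quartile). Exactly one of the two must be given.
#' @return A list of integer point-index vectors (highest-peak module first);
#'   empty list when no point passes.
#' @export
extract_top_modules <- function(map, cutoff = NULL, top_quantile = NULL) {
  stopifnot(inherits(map, "accuracy_map"))
  if (is.null(cutoff) == is.null(top_quantile)) {
    abort("give exactly one of cutoff or top_quantile")
  }
  v <- map$acc_total
  if (!is.null(top_quantile)) cutoff <- quantile(v, top_quantile, na.rm = TRUE, type = 7)
  sel <- which(!is.na(v) & v >= cutoff)
  if (length(sel) == 0) return(list())
  g <- neighborhood_graph(attr(map, "neighborhoods"))
  sub <- igraph::induced_subgraph(g, sel)
  comp <- igraph::components(sub)
  mods <- split(sel[seq_along(comp$membership)], comp$membership)
  peak <- vapply(mods, function(m) max(v[m]), numeric(1))
  unname(mods[order(peak, decreasing = TRUE)])
}

#' Correlate two accuracy maps
#'
#' Pearson correlation between the per-point total accuracies of two maps on
#' the same configuration, with a two-sided test — used to validate maps
#' across subsamples (e.g. one population vs the entire sample). When
#' `subset_quantile` is given, the correlation is additionally recomputed on
#' the points where `map_a` reaches that quantile of its own values (linear
#' interpolation convention), e.g. 0.75 for the third quartile.
#'
#' @param map_a,map_b Two `accuracy_map`s with identical points and space.
#' @param subset_quantile Optional quantile in (0, 1) for the subsetted
#'   correlation.
#' @return A one-row tibble `(r, p_value, n [, subset_r, subset_p, subset_n,
#'   subset_cutoff])`.
#' @export
compare_maps <- function(map_a, map_b, subset_quantile = NULL) {
  stopifnot(inherits(map_a, "accuracy_map"), inherits(map_b, "accuracy_map"))
  if (nrow(map_a) != nrow(map_b)) abort("maps differ in number of points")
  if (!identical(attr(map_a, "space"), attr(map_b, "space"))) {
    warn("comparing maps from different spaces")
  }
  a <- map_a$acc_total; b <- map_b$acc_total
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(a),
                  undefined = TRUE))
  }
  ct <- cor.test(a, b)
  out <- tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
  if (!is.null(subset_quantile)) {
    cutoff <- quantile(a, subset_quantile, type = 7)
    s <- a >= cutoff
    if (sum(s) >= 3 && sd(a[s]) > 1e-12 && sd(b[s]) > 1e-12) {
      cts <- cor.test(a[s], b[s])
      out$subset_r <- unname(cts$estimate)
      out$subset_p <- cts$p.value
    } else {
      out$subset_r <- NA_real_
      out$subset_p <- NA_real_
    }
    out$subset_n <- sum(s)
    out$subset_cutoff <- unname(cutoff)
  }
  out
}

#' @export
autoplot.accuracy_map <- function(object, axes = c("y", "z"), class = "total", ...) {
  cons <- attr(object, "consensus")
  df <- tibble(
    a = cons[, axes[1]], b = cons[, axes[2]],
    accuracy = object[[paste0("acc_", tolower(class))]]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, colour = .data$accuracy)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2(low = "#3B4CC0", mid = "#DDDDDD",
                                    high = "#B40426",
                                    midpoint = mean(range(df$accuracy, na.rm = TRUE))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = axes[1], y = axes[2],
                  title = paste0("accuracy map (", attr(object, "space"), " space)")) +
    ggplot2::theme_minimal()
}
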