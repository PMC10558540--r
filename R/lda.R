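# ---- internal two-class linear discriminant --------------------------------
# Pooled within-class covariance LDA. Written in-package because the mapping
# pipeline fits it ~1e5 times per map and needs (a) a deterministic ridge
# fallback when the pooled covariance of retained PC scores is singular and
# (b) explicit control of priors. Verified against MASS::lda in the tests.

fit_lda2 <- function(x, y, priors = c("proportional", "equal")) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  lev <- levels(y)
  if (length(lev) != 2) abort("two-class LDA needs exactly 2 levels")
  i1 <- which(y == lev[1]); i2 <- which(y == lev[2])
  if (length(i1) < 2 || length(i2) < 2) abort("each class needs at least 2 training specimens")
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[i2, , drop = FALSE])
  x1 <- sweep(x[i1, , drop = FALSE], 2, m1)
  x2 <- sweep(x[i2, , drop = FALSE], 2, m2)
  W <- (crossprod(x1) + crossprod(x2)) / (length(i1) + length(i2) - 2)
  w <- tryCatch(solve(W, m2 - m1), error = function(e) {
    # ridge fallback for singular pooled covariance
    k <- ncol(W)
    solve(W + diag(1e-8 * sum(diag(W)) / k, k), m2 - m1)
  })
  p1 <- if (priors == "proportional") length(i1) / length(y) else 0.5
  p2 <- 1 - p1
  # assign class 2 when w'x > cut
  cut <- sum(w * (m1 + m2)) / 2 - log(p2 / p1)
  list(w = w, cut = cut, levels = lev)
}

predict_lda2 <- function(fit, x) {
  x <- as.matrix(x)
  s <- drop(x %*% fit$w)
  factor(ifelse(s > fit$cut, fit$levels[2], fit$levels[1]), levels = fit$levels)
}

# ---- internal fast PCA for the hot loop ------------------------------------
# Centered SVD on the training block only; test rows are projected through the
# training mean and axes (the model is never refit on held-out specimens).
pca_truncate <- function(train, test, threshold) {
  ctr <- colMeans(train)
  tc <- sweep(train, 2, ctr)
  sv <- La.svd(tc, nu = 0)
  d2 <- sv$d^2
  keep <- d2 > d2[1] * 1e-24
  if (!any(keep)) abort("zero-variance training features")
  vf <- d2[keep] / sum(d2[keep])
  k <- which(cumsum(vf) >= threshold - 1e-12)[1]
  if (is.na(k)) k <- sum(keep)
  V <- t(sv$vt[seq_len(k), , drop = FALSE])
  list(train = tc %*% V, test = sweep(test, 2, ctr) %*% V, k = k)
}

# stratified train/test indices; specimens sampled by position within each
# class ordered by id, so results do not depend on storage order
stratified_split <- function(ids, labels, train_fraction) {
  idx <- lapply(levels(labels), function(l) {
    members <- which(labels == l)
    members <- members[order(ids[members])]
    n_tr <- floor(length(members) * train_fraction + 1e-9)
    if (n_tr < 2 || n_tr > length(members) - 1) {
      abort("train_fraction leaves a class without both training and test specimens")
    }
    take <- sample.int(length(members), n_tr)
    list(train = members[take], test = members[-take])
  })
  list(train = sort(unlist(lapply(idx, `[[`, "train"))),
       test = sort(unlist(lapply(idx, `[[`, "test"))))
}

accuracy_by_class <- function(truth, pred) {
  lev <- levels(truth)
  tot <- mean(pred == truth)
  accs <- vapply(lev, function(l) mean(pred[truth == l] == l), numeric(1))
  c(total = tot, accs)
}

#' Cross-validated linear discriminant accuracy
#'
#' Estimates how well a binary label (e.g. sex, F/M) can be predicted from a
#' feature matrix by repeated stratified train/test splits: per permutation,
#' a PCA is fitted on the training rows only, components are retained up to a
#' cumulative variance threshold, a two-class LDA with pooled within-class
#' covariance is fitted on the training scores, held-out rows are projected
#' through the training mean/axes and classified, and overall plus per-class
#' accuracies are recorded. Reported values are means (and SDs) over
#' permutations.
#'
#' @param features Numeric matrix, specimens x variables.
#' @param labels Factor or character vector of two classes (conventionally
#'   `"F"`/`"M"`), one per specimen.
#' @param train_fraction Fraction of each class used for training (default
#'   0.7, i.e. a 70/30 split).
#' @param n_perm Number of random splits (default 1000 for module-level runs).
#' @param variance_threshold Cumulative variance retained by the training PCA
#'   (default 0.9). Use 1 to keep all components.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param priors LDA priors: `"proportional"` to training class frequencies
#'   (default) or `"equal"`.
#' @param use_pca Apply the PCA reduction step? Disabled automatically for a
#'   single feature.
#' @return An `accuracy_result`: a one-row tibble with `acc_total`, `acc_f`,
#'   `acc_m`, their SDs over permutations, and the run parameters.
#' @export
lda_accuracy <- function(features, labels, train_fraction = 0.7, n_perm = 1000L,
                         variance_threshold = 0.9, seed = 1L,
                         priors = c("proportional", "equal"), use_pca = TRUE) {
  priors <- match.arg(priors)
  features <- as.matrix(features)
  labels <- as_fm_factor(labels)
  if (any(table(labels) < 2)) abort("both classes need at least 2 specimens")
  if (!(train_fraction > 0 && train_fraction < 1)) abort("train_fraction must be in (0,1)")
  if (n_perm < 1) abort("n_perm must be >= 1")
  ids <- rownames(features) %||% sprintf("s%06d", seq_len(nrow(features)))
  if (ncol(features) == 1) use_pca <- FALSE

  acc <- matrix(NA_real_, n_perm, 3)
  for (t in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 0L, t))
    sp <- stratified_split(ids, labels, train_fraction)
    xtr <- features[sp$train, , drop = FALSE]
    xte <- features[sp$test, , drop = FALSE]
    if (use_pca) {
      pr <- pca_truncate(xtr, xte, variance_threshold)
      xtr <- pr$train; xte <- pr$test
    }
    fit <- fit_lda2(xtr, labels[sp$train], priors)
    acc[t, ] <- accuracy_by_class(labels[sp$test], predict_lda2(fit, xte))
  }
  new_accuracy_result(acc, labels, n_perm, train_fraction, variance_threshold, seed)
}

as_fm_factor <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) abort("missing class labels")
  if (!all(labels %in% c("F", "M"))) abort("labels must be 'F' or 'M'")
  labels <- factor(labels, levels = c("F", "M"))
  if (nlevels(droplevels(labels)) != 2) abort("both classes F and M must be present")
  labels
}

new_accuracy_result <- function(acc, labels, n_perm, train_fraction,
                                variance_threshold, seed) {
  out <- tibble(
    acc_total = mean(acc[, 1]), acc_f = mean(acc[, 2]), acc_m = mean(acc[, 3]),
    sd_total = sd(acc[, 1]), sd_f = sd(acc[, 2]), sd_m = sd(acc[, 3]),
    n_perm = n_perm, train_fraction = train_fraction,
    variance_threshold = variance_threshold, seed = seed
  )
  class(out) <- c("accuracy_result", class(out))
  attr(out, "per_perm") <- acc
  out
}

#' @export
tidy.accuracy_result <- function(x, ...) {
  tibble(class = c("total", "F", "M"),
         accuracy = c(x$acc_total, x$acc_f, x$acc_m),
         sd = c(x$sd_total, x$sd_f, x$sd_m))
}

#' @export
glance.accuracy_result <- function(x, ...) {
  tibble(acc_total = x$acc_total, n_perm = x$n_perm,
         train_fraction = x$train_fraction,
         variance_threshold = x$variance_threshold)
}
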