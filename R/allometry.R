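#' Multivariate allometric regression of shape on size
#'
#' Ordinary least squares of every Procrustes-aligned coordinate on centroid
#' size (optionally log-transformed), fitted per group when group labels are
#' given, otherwise pooled. The stacked coefficient vector is the allometric
#' trajectory of a group; R-squared is the regression sum of squares over the
#' total, summed across all coordinates. Predicted shapes are evaluated at
#' each group's observed minimum and maximum predictor value.
#'
#' @param fit A `gpa_fit`.
#' @param groups Optional vector of `"F"`/`"M"` labels per specimen (defaults
#'   to the `sex` metadata carried by the fit, when complete).
#' @param log_predictor Regress on `log(centroid size)` instead of raw
#'   centroid size? Default `FALSE`.
#' @return An `allometry_model`: per-group tibble via [tidy()] (`group`, `n`,
#'   `r_squared`, `adj_r_squared`, predictor range), with coefficient vectors
#'   and predicted extreme shapes stored alongside. Pass to
#'   [trajectory_angle()] or see [angle_permutation_test()].
#' @export
allometric_regression <- function(fit, groups = NULL, log_predictor = FALSE) {
  stopifnot(inherits(fit, "gpa_fit"))
  y <- flatten_configs(fit$aligned)
  pred <- if (log_predictor) log(fit$csize) else fit$csize
  if (is.null(groups)) {
    sx <- fit$specimens$sex
    groups <- if (!is.null(sx) && !anyNA(sx)) sx else rep("all", nrow(y))
  }
  groups <- as.character(groups)
  k <- dim(fit$aligned)[1]

  fit_one <- function(rows) {
    x <- pred[rows]
    if (length(rows) < 3) abort("each group needs at least 3 specimens")
    if (sd(x) < 1e-12) abort("constant size predictor: allometric fit is singular")
    yg <- y[rows, , drop = FALSE]
    xc <- x - mean(x)
    ym <- colMeans(yg)
    yc <- sweep(yg, 2, ym)
    beta <- drop(crossprod(yc, xc)) / sum(xc^2)
    ss_reg <- sum(beta^2) * sum(xc^2)
    ss_tot <- sum(yc^2)
    r2 <- if (ss_tot > 0) ss_reg / ss_tot else 0
    n <- length(rows)
    pred_at <- function(x0) unflatten_config(ym + beta * (x0 - mean(x)), k)
    list(coefficients = beta, r_squared = r2,
         adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
         n = n, x_min = min(x), x_max = max(x),
         predicted_min_shape = pred_at(min(x)),
         predicted_max_shape = pred_at(max(x)),
         mean_shape = unflatten_config(ym, k))
  }

  glev <- unique(groups)
  fits <- lapply(glev, function(g) fit_one(which(groups == g)))
  names(fits) <- glev
  structure(list(fits = fits, log_predictor = log_predictor, n_points = k),
            class = "allometry_model")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat("<allometry_model> predictor: ",
      if (x$log_predictor) "log centroid size" else "centroid size", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname allometric_regression
#' @param x An `allometry_model`.
#' @param ... Unused.
#' @export
tidy.allometry_model <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$fits), function(g) {
    f <- x$fits[[g]]
    tibble(group = g, n = f$n, r_squared = f$r_squared,
           adj_r_squared = f$adj_r_squared, x_min = f$x_min, x_max = f$x_max)
  }))
}

#' @rdname allometric_regression
#' @export
glance.allometry_model <- function(x, ...) {
  tibble(n_groups = length(x$fits), log_predictor = x$log_predictor,
         n_points = x$n_points)
}

#' Angle between two allometric trajectories
#'
#' The angle (degrees, in \[0, 180\]) between the unit-normalized stacked
#' coefficient vectors of two allometric regressions; 0 means identical
#' direction of shape change with size, 90 orthogonal directions.
#'
#' @param a,b Either two `allometry_model` objects (their first groups are
#'   used), a single two-group `allometry_model` (leave `b` `NULL`), or two
#'   numeric coefficient vectors.
#' @return Angle in degrees.
#' @export
trajectory_angle <- function(a, b = NULL) {
  coef_of <- function(m, which = 1) {
    if (inherits(m, "allometry_model")) m$fits[[which]]$coefficients else as.numeric(m)
  }
  if (is.null(b)) {
    if (!inherits(a, "allometry_model") || length(a$fits) < 2) {
      abort("need two trajectories: a two-group model or two arguments")
    }
    v1 <- coef_of(a, 1); v2 <- coef_of(a, 2)
  } else {
    v1 <- coef_of(a); v2 <- coef_of(b)
  }
  if (length(v1) != length(v2)) abort("coefficient vectors differ in length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-300 || n2 < 1e-300) abort("zero-norm coefficient vector: angle undefined")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Permutation test for allometric trajectory divergence
#'
#' Tests whether the angle between the group-wise allometric trajectories
#' (e.g. female vs male) is larger than expected when group labels carry no
#' information: labels are shuffled (group sizes preserved), the two
#' regressions refitted and the angle recomputed for each permutation.
#' `p = (# permuted angles >= observed + 1) / (n_perm + 1)`.
#'
#' @param fit A `gpa_fit`.
#' @param labels `"F"`/`"M"` labels per specimen (defaults to the `sex`
#'   metadata of the fit).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param log_predictor Passed to [allometric_regression()].
#' @return A one-row tibble `(angle, p_value, n_perm)`.
#' @export
angle_permutation_test <- function(fit, labels = NULL, n_perm = 1000L, seed = 1L,
                                   log_predictor = FALSE) {
  stopifnot(inherits(fit, "gpa_fit"))
  if (is.null(labels)) labels <- fit$specimens$sex
  labels <- as_fm_factor(labels)
  if (any(table(labels) < 3)) abort("both groups need at least 3 specimens")
  obs <- trajectory_angle(allometric_regression(fit, labels, log_predictor))
  n <- length(labels)
  exceed <- 0L
  for (t in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 11L, t))
    lab <- labels[sample.int(n)]
    ang <- trajectory_angle(allometric_regression(fit, lab, log_predictor))
    if (ang >= obs - 1e-12) exceed <- exceed + 1L
  }
  tibble(angle = obs, p_value = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

#' @export
autoplot.allometry_model <- function(object, fit = NULL, ...) {
  # projection of each group's shapes on its own trajectory vs predictor
  df <- dplyr::bind_rows(lapply(names(object$fits), function(g) {
    f <- object$fits[[g]]
    tibble(group = g,
           predictor = c(f$x_min, f$x_max),
           shape_score = c(0, sqrt(sum((f$predicted_max_shape -
                                          f$predicted_min_shape)^2))))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$predictor, .data$shape_score,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (object$log_predictor) "log centroid size" else "centroid size",
                  y = "shape change along trajectory", colour = NULL) +
    ggplot2::theme_minimal()
}
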