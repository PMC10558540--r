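#' Principal component analysis of shape (or form) variables
#'
#' Centered singular-value-decomposition PCA, as used throughout the
#' pipeline. Component signs are fixed deterministically: each axis is
#' flipped so that its largest-magnitude loading is positive.
#'
#' @param x A numeric matrix (specimens x variables), e.g. flattened aligned
#'   coordinates or a form matrix.
#' @return A `shape_pca` object with `mean`, `rotation` (orthonormal axes in
#'   columns), `eigenvalues`, `scores`, `variance_fraction` and a
#'   `degenerate` flag (all-zero variance). `tidy()` returns the per-component
#'   variance table; `pca_scores()` the score tibble.
#' @export
shape_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 specimens")
  if (!all(is.finite(x))) abort("non-finite entries in data matrix")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  degenerate <- sum(ev) < 1e-300
  rot <- p$rotation
  sco <- p$x
  # deterministic sign: largest-|loading| entry of each axis is positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  vf <- if (degenerate) rep(0, length(ev)) else ev / sum(ev)
  structure(list(
    mean = p$center, rotation = rot, eigenvalues = ev, scores = sco,
    variance_fraction = vf, degenerate = degenerate, n = nrow(x)
  ), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca> ", x$n, " specimens, ", ncol(x$rotation), " components",
      if (x$degenerate) " (degenerate: zero variance)", "\n", sep = "")
  v <- head(round(100 * x$variance_fraction, 2), 5)
  cat("  % variance: ", paste(v, collapse = ", "),
      if (length(x$variance_fraction) > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' @rdname shape_pca
#' @param x A `shape_pca`.
#' @param ... Unused.
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction)
  )
}

#' @rdname shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(n = x$n, n_components = ncol(x$rotation), degenerate = x$degenerate)
}

#' @rdname shape_pca
#' @export
pca_scores <- function(x) {
  stopifnot(inherits(x, "shape_pca"))
  out <- as_tibble(x$scores, .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(ncol(out)))
  out$specimen_id <- rownames(x$scores) %||% as.character(seq_len(nrow(x$scores)))
  dplyr::relocate(out, "specimen_id")
}

#' Form matrix: shape variables plus log centroid size
#'
#' Form (size-and-shape) space re-introduces size into a shape analysis by
#' appending the natural log of each specimen's original centroid size as one
#' extra column to the flattened Procrustes-aligned coordinates.
#'
#' @param fit A `gpa_fit` computed with `scale = TRUE`.
#' @return A numeric matrix `n_specimens x (3 * n_points + 1)`; the last
#'   column is named `log_csize`.
#' @export
form_matrix <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  if (!fit$scaled) abort("form space needs a GPA fitted with scale = TRUE")
  if (is.null(fit$csize)) abort("centroid sizes missing from the fit")
  m <- cbind(flatten_configs(fit$aligned), log_csize = log(fit$csize))
  rownames(m) <- dimnames(fit$aligned)[[3]]
  m
}

#' Shape matrix of flattened aligned coordinates
#'
#' @param fit A `gpa_fit`.
#' @return `n_specimens x 3 n_points` matrix (x then y then z blocks).
#' @export
shape_matrix <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  m <- flatten_configs(fit$aligned)
  rownames(m) <- dimnames(fit$aligned)[[3]]
  m
}

#' Number of components needed to reach a variance threshold
#'
#' @param p A `shape_pca` (or anything with a `variance_fraction` field).
#' @param threshold Fraction of total variance to retain, in (0, 1].
#' @return The smallest k whose first k components reach the threshold
#'   (at least 1).
#' @export
n_components_for_variance <- function(p, threshold) {
  if (!(threshold > 0 && threshold <= 1)) abort("threshold must be in (0, 1]")
  vf <- p$variance_fraction
  nonnull <- vf > 1e-12
  cum <- cumsum(vf)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- max(1L, sum(nonnull))
  max(1L, min(k, max(1L, sum(nonnull))))
}

#' @export
autoplot.shape_pca <- function(object, x = 1, y = 2, colour = NULL, ...) {
  sc <- pca_scores(object)
  vf <- round(100 * object$variance_fraction, 2)
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[paste0("PC", x)]],
                                        .data[[paste0("PC", y)]]))
  if (!is.null(colour)) {
    sc$colour <- colour
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[paste0("PC", x)]],
                                          .data[[paste0("PC", y)]],
                                          colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC%d (%.2f%%)", x, vf[x]),
                  y = sprintf("PC%d (%.2f%%)", y, vf[y])) +
    ggplot2::theme_minimal()
}
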