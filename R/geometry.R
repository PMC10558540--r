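#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all points from their centroid.
#'
#' @param x An `n_points x 3` numeric matrix, or a `specimen_set` (in which
#'   case one size per specimen is returned).
#' @return A positive scalar (mm), or a tibble `(specimen_id, csize)` for a
#'   `specimen_set`. Zero only when all points coincide.
#' @examples
#' cube <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5)))
#' centroid_size(cube)  # sqrt(6)
#' @export
centroid_size <- function(x) {
  if (inherits(x, "specimen_set")) {
    arr <- x$array
    cs <- vapply(seq_len(dim(arr)[3]),
                 function(i) centroid_size(arr[, , i]), numeric(1))
    return(tibble(specimen_id = dimnames(arr)[[3]], csize = cs))
  }
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("empty configuration")
  if (!all(is.finite(x))) abort("non-finite coordinates")
  xc <- sweep(x, 2, colMeans(x))
  sqrt(sum(xc^2))
}

#' Ordinary Procrustes superimposition onto a fixed reference
#'
#' Translates, optionally scales, and rotates one configuration to minimize
#' the summed squared distance to a reference with the same points. The
#' rotation is always proper (determinant +1; reflections are never used).
#'
#' @param x `n_points x 3` matrix to align.
#' @param reference `n_points x 3` reference matrix.
#' @param scale Should an optimal scaling factor be fitted? Default `FALSE`.
#' @return A list with `aligned` (matrix in the reference frame), `rotation`
#'   (3 x 3), `scale`, and `residual` (root summed squared distance after the
#'   fit).
#' @export
opa_align <- function(x, reference, scale = FALSE) {
  x <- as.matrix(x); reference <- as.matrix(reference)
  if (!identical(dim(x), dim(reference))) abort("x and reference must share dimensions")
  cpp_opa(x, reference, scale)
}

#' Generalized Procrustes analysis
#'
#' Iteratively centers all specimens, optionally rescales each to unit
#' centroid size, rotates each onto the current consensus and re-estimates
#' the consensus, until the root-mean-square consensus change falls below
#' `tol`. Original centroid sizes are stored regardless of scaling, so that
#' form-space analyses can re-attach size.
#'
#' @param x A `specimen_set` or an `n_points x 3 x n` array.
#' @param scale Remove size by scaling every specimen to unit centroid size
#'   (shape space)? Default `TRUE`.
#' @param tol Convergence tolerance on the RMS consensus change.
#' @param max_iter Maximum number of alignment sweeps.
#' @return A `gpa_fit` object: `aligned` (array), `csize` (original centroid
#'   sizes), `consensus` (arithmetic mean of the aligned coordinates),
#'   `scaled`, `iterations`, `final_change`, plus the specimen metadata when
#'   available. Use [tidy()] for the aligned coordinates in long form and
#'   [glance()] for the convergence record.
#' @export
gpa <- function(x, scale = TRUE, tol = 1e-10, max_iter = 100L) {
  if (inherits(x, "specimen_set")) {
    arr <- x$array
    specimens <- x$specimens
    points <- x$points
  } else {
    arr <- x
    specimens <- tibble(specimen_id = dimnames(arr)[[3]] %||% paste0("s", seq_len(dim(arr)[3])))
    points <- NULL
  }
  if (dim(arr)[3] < 2) abort("GPA needs at least 2 specimens")
  res <- tryCatch(
    cpp_gpa(arr, scale, tol, max_iter),
    error = function(e) {
      abort(paste0("GPA failed: ", conditionMessage(e)))
    }
  )
  if (!res$converged) {
    warn(sprintf("GPA did not converge in %d iterations (final change %.3g)",
                 max_iter, res$final_change))
  }
  # canonical orientation: rotate the whole solution onto the principal axes
  # of the consensus (deterministic signs), so the aligned coordinates do not
  # depend on the input specimens' arbitrary original orientations
  rot <- canonical_rotation(res$consensus)
  aligned <- res$aligned
  for (i in seq_len(dim(aligned)[3])) aligned[, , i] <- aligned[, , i] %*% rot
  dimnames(aligned) <- dimnames(arr)
  consensus <- res$consensus %*% rot
  dimnames(consensus) <- dimnames(arr)[1:2]
  structure(list(
    aligned = aligned,
    csize = setNames(as.numeric(res$csize), dimnames(arr)[[3]]),
    consensus = consensus,
    scaled = scale,
    iterations = res$iterations,
    final_change = res$final_change,
    specimens = specimens,
    points = points
  ), class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  cat("<gpa_fit> ", d[3], " specimens x ", d[1], " points; ",
      if (x$scaled) "shape space (unit centroid size)" else "size preserved",
      "\n  converged in ", x$iterations, " iterations (final change ",
      format(x$final_change, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname gpa
#' @param x A `gpa_fit`.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  arr <- x$aligned
  k <- dim(arr)[1]; n <- dim(arr)[3]
  out <- tibble(
    specimen_id = rep(dimnames(arr)[[3]], each = k),
    point_id = rep(dimnames(arr)[[1]], times = n),
    x = as.vector(arr[, 1, ]),
    y = as.vector(arr[, 2, ]),
    z = as.vector(arr[, 3, ])
  )
  dplyr::left_join(out, x$specimens, by = "specimen_id")
}

#' @rdname gpa
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble(
    n_specimens = dim(x$aligned)[3],
    n_points = dim(x$aligned)[1],
    scaled = x$scaled,
    iterations = x$iterations,
    final_change = x$final_change,
    mean_csize = mean(x$csize)
  )
}

# proper rotation onto the principal axes of a centered configuration, with
# deterministic signs (largest-|entry| of each axis positive; det fixed to +1
# by flipping the third axis if needed)
canonical_rotation <- function(consensus) {
  sv <- svd(consensus)
  V <- sv$v
  # sign rule on the rotated coordinates (frame-independent): the
  # largest-|value| coordinate along each axis is positive
  sc <- consensus %*% V
  for (j in 1:3) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# flatten an aligned k x 3 x n array to n x 3k (x1..xk, y1..yk, z1..zk)
flatten_configs <- function(arr) {
  k <- dim(arr)[1]; n <- dim(arr)[3]
  m <- matrix(aperm(arr, c(1, 2, 3)), nrow = k * 3, ncol = n)
  t(m)
}

unflatten_config <- function(v, k) {
  matrix(v, nrow = k, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

#' Procrustes distance matrix between aligned specimens
#'
#' @param fit A `gpa_fit`.
#' @return A `dist` object of root summed squared coordinate differences.
#' @export
procrustes_dist <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  stats::dist(flatten_configs(fit$aligned))
}

#' Symmetrize bilateral landmark configurations
#'
#' Removes the asymmetric shape component from each specimen by averaging the
#' configuration with its reflected and relabeled copy: one coordinate axis
#' is negated, each left/right pair is swapped (midline points keep their
#' labels), the reflected copy is superimposed on the original by ordinary
#' Procrustes analysis without scaling, and the two are averaged. The step is
#' iterated to a fixed point, so the result is invariant under
#' reflect-and-relabel.
#'
#' @param x A `specimen_set` whose point scheme declares bilateral pairs
#'   (and, implicitly, midline points).
#' @param tol Fixed-point tolerance (mm).
#' @return A `specimen_set` of symmetrized configurations.
#' @export
symmetrize <- function(x, tol = 1e-12) {
  stopifnot(inherits(x, "specimen_set"))
  pm <- pairs_matrix(x)
  if (nrow(pm) == 0 && length(midline_indices(x)) == 0) {
    abort("symmetrize needs a point scheme with bilateral pairs/midline points")
  }
  perm <- seq_len(dim(x$array)[1])
  perm[pm[, 1]] <- pm[, 2]
  perm[pm[, 2]] <- pm[, 1]
  arr <- x$array
  for (i in seq_len(dim(arr)[3])) {
    X <- arr[, , i]
    for (iter in 1:20) {
      Xr <- X
      Xr[, 1] <- -Xr[, 1]
      Xr <- Xr[perm, , drop = FALSE]
      fit <- cpp_opa(Xr, X, FALSE)
      S <- (X + fit$aligned) / 2
      delta <- max(abs(S - X))
      X <- S
      if (delta < tol) break
    }
    arr[, , i] <- X
  }
  structure(list(array = arr, specimens = x$specimens, points = x$points),
            class = "specimen_set")
}

# residual of a configuration under reflect-relabel-OPA; 0 for symmetric shapes
reflect_relabel_residual <- function(X, pairs, tol_scale = 1) {
  perm <- seq_len(nrow(X))
  perm[pairs[, 1]] <- pairs[, 2]
  perm[pairs[, 2]] <- pairs[, 1]
  Xr <- X
  Xr[, 1] <- -Xr[, 1]
  Xr <- Xr[perm, , drop = FALSE]
  cpp_opa(Xr, X, FALSE)$residual
}
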