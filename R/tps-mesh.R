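#' Thin-plate-spline warp in 3D
#'
#' Builds the 3D thin-plate-spline interpolant (radial kernel `U(r) = r` plus
#' an affine term) that maps `source_pts` exactly onto `target_pts`, and
#' evaluates it at `query_pts`. Used to deform a surface along with a
#' landmark displacement when rendering shape differences.
#'
#' @param source_pts,target_pts `n x 3` matrices of corresponding points
#'   (`n >= 4`, not coplanar).
#' @param query_pts `m x 3` matrix of points to map.
#' @return `m x 3` matrix of warped query points.
#' @export
tps_warp <- function(source_pts, target_pts, query_pts) {
  S <- as.matrix(source_pts); T_ <- as.matrix(target_pts); Q <- as.matrix(query_pts)
  n <- nrow(S)
  if (n < 4) abort("thin-plate spline needs at least 4 source points")
  if (nrow(T_) != n) abort("source and target must have the same number of points")
  K <- as.matrix(stats::dist(S))
  P <- cbind(1, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(T_, matrix(0, 4, 3))
  coef <- tryCatch(solve(L, rhs), error = function(e) {
    abort("singular thin-plate-spline system (coplanar or duplicated source points)")
  })
  W <- coef[seq_len(n), , drop = FALSE]
  A <- coef[n + 1:4, , drop = FALSE]
  U <- sqrt(outer(rowSums(Q^2), rep(1, n)) + outer(rep(1, nrow(Q)), rowSums(S^2)) -
              2 * Q %*% t(S))
  U[U < 0 | is.nan(U)] <- 0
  cbind(1, Q) %*% A + U %*% W
}

# triangle areas for a faces matrix (rows of 3 vertex indices)
triangle_areas <- function(coords, faces) {
  a <- coords[faces[, 1], , drop = FALSE]
  b <- coords[faces[, 2], , drop = FALSE]
  c_ <- coords[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

validate_faces <- function(faces, n_points) {
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) abort("faces must be an m x 3 index matrix")
  if (any(faces < 1) || any(faces > n_points)) abort("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3])) {
    abort("faces must have 3 distinct vertices")
  }
  storage.mode(faces) <- "integer"
  faces
}

# per-vertex area: one third of the summed areas of incident triangles
vertex_areas <- function(coords, faces) {
  ta <- triangle_areas(coords, faces)
  va <- numeric(nrow(coords))
  for (j in 1:3) {
    s <- tapply(ta, faces[, j], sum)
    va[as.integer(names(s))] <- va[as.integer(names(s))] + s
  }
  va / 3
}

#' Per-vertex area-change map between two configurations
#'
#' Compares local surface area around every point of a target configuration
#' with the same quantity on a reference (e.g. the consensus shape), using a
#' shared triangulation. The per-vertex area is one third of the summed areas
#' of the incident triangles; the map is the target/reference ratio, so 1
#' means unchanged, values above 1 expansion and below 1 contraction.
#'
#' @param reference,target `n x 3` coordinate matrices on the same point
#'   scheme.
#' @param faces `m x 3` integer matrix of triangle vertex indices (1-based).
#' @return A tibble `(point_id, area_reference, area_target, ratio)`.
#' @export
area_change_map <- function(reference, target, faces) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!identical(dim(reference), dim(target))) abort("reference and target must match")
  faces <- validate_faces(faces, nrow(reference))
  orphan <- setdiff(seq_len(nrow(reference)), unique(as.vector(faces)))
  if (length(orphan) > 0) {
    abort(paste0("vertices with no incident face (area ratio undefined): ",
                 paste(orphan, collapse = ", ")))
  }
  ar <- vertex_areas(reference, faces)
  at <- vertex_areas(target, faces)
  ids <- rownames(reference) %||% paste0("p", seq_len(nrow(reference)))
  tibble(point_id = ids, area_reference = ar, area_target = at, ratio = at / ar)
}

# area-weighted outward vertex normals of a closed triangulated surface
vertex_normals <- function(coords, faces) {
  a <- coords[faces[, 1], , drop = FALSE]
  b <- coords[faces[, 2], , drop = FALSE]
  c_ <- coords[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])  # 2*area-weighted face normal
  vn <- matrix(0, nrow(coords), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      s <- tapply(cr[, d], faces[, j], sum)
      vn[as.integer(names(s)), d] <- vn[as.integer(names(s)), d] + s
    }
  }
  nrm <- sqrt(rowSums(vn^2))
  if (any(nrm < 1e-300)) abort("outward normal undefined at degenerate vertices")
  vn <- vn / nrm
  # orient outward relative to the centroid
  ctr <- colMeans(coords)
  flip <- rowSums(vn * sweep(coords, 2, ctr)) < 0
  vn[flip, ] <- -vn[flip, ]
  vn
}
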