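#' Base ellipsoid shape with bilateral symmetry and a triangulation
#'
#' Builds a quasi-uniform, exactly bilaterally symmetric point lattice on an
#' ellipsoid, together with a valid triangulation: two poles on the first
#' (left-right) axis and an odd number of latitude rings, each ring carrying
#' the same number of longitudes with a seeded phase offset shared between
#' mirrored rings. Reflection across the first axis maps the lattice onto
#' itself: mirrored rings swap (bilateral pairs), the equatorial ring and no
#' other points lie on the symmetry plane (midline), and the two poles form a
#' pair. The realized point count is the nearest lattice size
#' `2 + n_rings * n_long` to the request.
#'
#' @param n_points Requested number of points (>= 16).
#' @param semi_axes Ellipsoid semi-axes `(a, b, c)`; `a` is the bilateral
#'   axis.
#' @param seed Integer seed for the per-ring longitude phases.
#' @return A list with `coordinates` (`n x 3`, centered), `points` (point
#'   scheme tibble with roles/sides/pairs), `faces` (triangulation) and
#'   `mean_spacing` (mean nearest-neighbor distance).
#' @export
make_base_shape <- function(n_points = 150L, semi_axes = c(1, 0.8, 0.7), seed = 1L) {
  if (n_points < 16) abort("base shape needs at least 16 points")
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  n_rings <- round(sqrt((n_points - 2) / 2))
  if (n_rings %% 2 == 0) n_rings <- n_rings + 1
  n_rings <- max(3L, as.integer(n_rings))
  n_long <- max(4L, as.integer(round((n_points - 2) / n_rings)))
  k <- 2L + n_rings * n_long

  set.seed(derive_seed(seed, 99L, 0L))
  half <- (n_rings - 1) / 2
  phase <- runif(half + 1, 0, 2 * pi / n_long)  # shared by mirrored rings

  theta <- pi * seq_len(n_rings) / (n_rings + 1)
  coords <- matrix(NA_real_, k, 3)
  coords[1, ] <- c(semi_axes[1], 0, 0)   # +x pole
  coords[2, ] <- c(-semi_axes[1], 0, 0)  # -x pole
  idx <- function(ring, j) 2L + (ring - 1L) * n_long + j
  for (ring in seq_len(n_rings)) {
    ph <- phase[min(ring, n_rings + 1 - ring)]
    phi <- ph + 2 * pi * (seq_len(n_long) - 1) / n_long
    coords[idx(ring, seq_len(n_long)), ] <- cbind(
      semi_axes[1] * cos(theta[ring]),
      semi_axes[2] * sin(theta[ring]) * cos(phi),
      semi_axes[3] * sin(theta[ring]) * sin(phi)
    )
  }
  coords <- sweep(coords, 2, colMeans(coords))
  rownames(coords) <- paste0("p", seq_len(k))

  # pairing: ring r <-> ring n_rings + 1 - r, same longitude; poles pair up
  mid_ring <- (n_rings + 1) / 2
  side <- rep(NA_character_, k)
  pair <- rep(NA_integer_, k)
  side[1] <- "L"; side[2] <- "R"; pair[1] <- pair[2] <- 1L
  next_pair <- 2L
  for (ring in seq_len(mid_ring - 1)) {
    for (j in seq_len(n_long)) {
      i_l <- idx(ring, j); i_r <- idx(n_rings + 1L - ring, j)
      side[i_l] <- "L"; side[i_r] <- "R"
      pair[i_l] <- pair[i_r] <- next_pair
      next_pair <- next_pair + 1L
    }
  }
  side[idx(mid_ring, seq_len(n_long))] <- "M"

  faces <- ellipsoid_faces(n_rings, n_long)
  nn <- as.matrix(stats::dist(coords))
  diag(nn) <- Inf
  list(
    coordinates = coords,
    points = tibble(point_id = rownames(coords),
                    role = "semilandmark", side = side, pair = pair),
    faces = faces,
    mean_spacing = mean(apply(nn, 1, min))
  )
}

# triangle fan at both poles plus quad strips between rings
ellipsoid_faces <- function(n_rings, n_long) {
  idx <- function(ring, j) 2L + (ring - 1L) * n_long + ((j - 1L) %% n_long) + 1L
  faces <- list()
  for (j in seq_len(n_long)) {
    faces[[length(faces) + 1]] <- c(1L, idx(1, j), idx(1, j + 1))
    faces[[length(faces) + 1]] <- c(2L, idx(n_rings, j + 1), idx(n_rings, j))
  }
  for (ring in seq_len(n_rings - 1)) {
    for (j in seq_len(n_long)) {
      a <- idx(ring, j); b <- idx(ring, j + 1)
      c_ <- idx(ring + 1, j); d <- idx(ring + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, c_, b)
      faces[[length(faces) + 1]] <- c(b, c_, d)
    }
  }
  do.call(rbind, faces)
}

#' Simulate a landmark dataset with known ground truth
#'
#' Generates a two-group (F/M) sample of 3D landmark configurations around a
#' shared symmetric base shape, with all the structure the mapping pipeline
#' is meant to detect planted explicitly: a localized mean-shape difference
#' (group M displaced along outward normals or a fixed vector on a chosen
#' point patch), group size dimorphism (log-normal centroid sizes),
#' shared or diverging allometric shape-size regressions, frame-independent
#' digitization noise (applied after a random rotation/translation of each
#' specimen), and optional replicate digitizations for repeatability studies.
#'
#' Defaults emulate a human-cranium-like study: mean centroid sizes 950 mm
#' (F) and 1000 mm (M) (about 5% size dimorphism), 3.5% log-size spread and
#' 0.5 mm isotropic landmark noise.
#'
#' @param n_f,n_m Specimens per group.
#' @param n_points Requested base-shape size (see [make_base_shape()]).
#' @param semi_axes Base ellipsoid semi-axes.
#' @param effect_indices Integer indices of the points carrying the localized
#'   group difference (empty for a null dataset).
#' @param effect_size Displacement magnitude as a fraction of the base
#'   shape's mean nearest-neighbor spacing.
#' @param effect_direction `"normal"` (outward vertex normals) or a fixed
#'   3-vector.
#' @param size_mean Named vector `c(f = , m = )` of group mean centroid sizes
#'   (mm).
#' @param size_sdlog Named vector of log-scale size SDs per group.
#' @param allometry Optional list `list(f = , m = )` of `n_points x 3` (or
#'   length `3 n_points`) direction matrices; see [allometry_vectors()].
#' @param allometry_strength Shape displacement per unit log-size deviation.
#' @param noise_sd Isotropic digitization noise SD (mm), applied per
#'   coordinate after the random rigid motion; redrawn per replicate.
#' @param individual_sd Isotropic among-individual (biological) shape
#'   variation SD (mm), drawn once per individual and shared by its
#'   replicates (default 0). The among:within variance ratio of a
#'   repeatability design is `individual_sd^2 : noise_sd^2`.
#' @param n_replicates Digitizations per specimen (replicates share geometry,
#'   differ in rigid motion and noise; replicate ids get suffix `_r<j>` and
#'   `replicate_of` set).
#' @param seed Integer seed; fixed seed gives a bit-identical dataset.
#' @return A `specimen_set`; the planted parameters (including the realized
#'   base shape, faces, patch indices and mean spacing) are stored in the
#'   `"ground_truth"` attribute.
#' @export
simulate_landmarks <- function(n_f = 60L, n_m = 60L, n_points = 150L,
                               semi_axes = c(1, 0.8, 0.7),
                               effect_indices = integer(0), effect_size = 0,
                               effect_direction = "normal",
                               size_mean = c(f = 950, m = 1000),
                               size_sdlog = c(f = 0.035, m = 0.035),
                               allometry = NULL, allometry_strength = 0,
                               noise_sd = 0.5, individual_sd = 0,
                               n_replicates = 1L, seed = 1L) {
  if (n_f < 1 || n_m < 1) abort("both groups must be non-empty")
  if (noise_sd < 0 || any(size_sdlog < 0)) abort("noise_sd and size_sdlog must be >= 0")
  if (is.null(names(size_mean))) names(size_mean) <- c("f", "m")
  if (is.null(names(size_sdlog))) names(size_sdlog) <- c("f", "m")
  base <- make_base_shape(n_points, semi_axes, seed)
  B <- base$coordinates
  k <- nrow(B)
  B <- B / centroid_size(B)  # unit centroid size; sizes are planted exactly
  spacing <- base$mean_spacing / centroid_size(base$coordinates)
  if (length(effect_indices) > 0 &&
      (any(effect_indices < 1) || any(effect_indices > k))) {
    abort("effect_indices out of range for the realized base shape")
  }

  dir_mat <- NULL
  if (length(effect_indices) > 0 && effect_size != 0) {
    if (identical(effect_direction, "normal")) {
      dir_mat <- vertex_normals(B, base$faces)[effect_indices, , drop = FALSE]
    } else {
      v <- as.numeric(effect_direction)
      if (length(v) != 3 || sum(v^2) == 0) abort("effect_direction must be 'normal' or a 3-vector")
      dir_mat <- matrix(v / sqrt(sum(v^2)), length(effect_indices), 3, byrow = TRUE)
    }
  }

  av <- NULL
  if (!is.null(allometry)) {
    av <- lapply(allometry, function(m) {
      m <- if (is.matrix(m)) m else unflatten_config(as.numeric(m), k)
      if (nrow(m) != k) abort("allometry vectors must match the realized point count")
      m / sqrt(sum(m^2))
    })
    if (is.null(av$f) || is.null(av$m)) abort("allometry must be a list with elements f and m")
  }

  n <- n_f + n_m
  sexes <- rep(c("F", "M"), c(n_f, n_m))
  g <- tolower(sexes)
  spec_ids <- sprintf("%s%03d", sexes, c(seq_len(n_f), seq_len(n_m)))
  mean_log <- mean(log(size_mean[g]))  # design-expected mean log size

  total <- n * n_replicates
  arr <- array(NA_real_, dim = c(k, 3, total),
               dimnames = list(rownames(B), c("x", "y", "z"), NULL))
  ids <- character(total)
  rep_of <- rep(NA_character_, total)
  slot <- 0L
  csize_true <- numeric(n)

  set.seed(derive_seed(seed, 1L, 0L))
  for (i in seq_len(n)) {
    shape <- B
    if (!is.null(dir_mat) && sexes[i] == "M") {
      shape[effect_indices, ] <- shape[effect_indices, ] +
        effect_size * spacing * dir_mat
    }
    log_s <- rnorm(1, log(size_mean[g[i]]), size_sdlog[g[i]])
    if (!is.null(av) && allometry_strength != 0) {
      shape <- shape + allometry_strength * (log_s - mean_log) * av[[g[i]]]
    }
    csize_true[i] <- exp(log_s)
    X0 <- shape / centroid_size(shape) * csize_true[i]
    if (individual_sd > 0) {
      # biological (among-individual) shape variation, shared by replicates
      X0 <- X0 + matrix(rnorm(3 * k, 0, individual_sd), k, 3)
    }
    for (j in seq_len(n_replicates)) {
      R <- random_rotation()
      tr <- rnorm(3, 0, 50)
      X <- X0 %*% R + matrix(tr, k, 3, byrow = TRUE)
      if (noise_sd > 0) X <- X + matrix(rnorm(3 * k, 0, noise_sd), k, 3)
      slot <- slot + 1L
      arr[, , slot] <- X
      ids[slot] <- if (n_replicates == 1) spec_ids[i] else paste0(spec_ids[i], "_r", j)
      if (n_replicates > 1) rep_of[slot] <- spec_ids[i]
    }
  }
  dimnames(arr)[[3]] <- ids
  specimens <- tibble(
    specimen_id = ids,
    sex = rep(sexes, each = n_replicates),
    population = "synthetic",
    replicate_of = rep_of
  )
  out <- as_specimen_set(arr, specimens = specimens, points = base$points)
  attr(out, "ground_truth") <- list(
    base_shape = B, faces = base$faces, mean_spacing = spacing,
    effect_indices = effect_indices, effect_size = effect_size,
    effect_mm = effect_size * spacing * exp(mean_log),
    size_mean = size_mean, size_sdlog = size_sdlog,
    allometry = av, allometry_strength = allometry_strength,
    noise_sd = noise_sd, individual_sd = individual_sd,
    csize_true = csize_true, seed = seed
  )
  out
}

# uniform random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Pair of allometric direction fields at a planted angle
#'
#' Constructs two unit direction fields over a configuration whose stacked
#' coefficient vectors meet at a specified angle — used to plant a known
#' allometric trajectory divergence between groups.
#'
#' @param n_points Number of points of the target configuration.
#' @param angle Planted angle in degrees.
#' @param seed Integer seed.
#' @return `list(f = , m = )` of `n_points x 3` unit matrices.
#' @export
allometry_vectors <- function(n_points, angle = 0, seed = 1L) {
  set.seed(derive_seed(seed, 2L, 0L))
  p <- 3 * n_points
  v1 <- rnorm(p); v1 <- v1 / sqrt(sum(v1^2))
  u <- rnorm(p); u <- u - sum(u * v1) * v1; u <- u / sqrt(sum(u^2))
  a <- angle * pi / 180
  v2 <- cos(a) * v1 + sin(a) * u
  list(f = unflatten_config(v1, n_points), m = unflatten_config(v2, n_points))
}

#' Shape matrix with planted variance fractions for model terms
#'
#' Direct construction for validating [procrustes_lm()]: builds a
#' specimens-by-variables response whose expected sequential variance
#' fractions for a continuous `size` term and a binary `sex` term are the
#' planted values, with the remainder isotropic noise. Predictors are
#' returned alongside; `sex` is orthogonalized against `size` so the
#' sequential decomposition matches the planted fractions.
#'
#' @param n Specimens.
#' @param n_vars Response variables.
#' @param r2_size,r2_sex Planted variance fractions (sum < 1).
#' @param seed Integer seed.
#' @return `list(y = matrix, data = tibble(size, sex))`.
#' @export
simulate_variance_partition <- function(n = 200L, n_vars = 60L,
                                        r2_size = 0.4, r2_sex = 0.1, seed = 1L) {
  if (r2_size + r2_sex >= 1) abort("planted fractions must sum to less than 1")
  set.seed(derive_seed(seed, 3L, 0L))
  size <- rnorm(n)
  sex <- rep(c("F", "M"), length.out = n)
  sx <- ifelse(sex == "M", 1, -1)
  # orthogonalize and standardize the component scores
  z1 <- scale(size)[, 1]; z1 <- z1 / sqrt(sum(z1^2))
  z2 <- scale(stats::resid(stats::lm(sx ~ size)))[, 1]; z2 <- z2 / sqrt(sum(z2^2))
  u1 <- rnorm(n_vars); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(n_vars); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  E <- matrix(rnorm(n * n_vars), n, n_vars)
  E <- sweep(E, 2, colMeans(E))
  E <- E - z1 %o% drop(crossprod(z1, E)) - z2 %o% drop(crossprod(z2, E))
  E <- E / sqrt(sum(E^2))
  y <- sqrt(r2_size) * z1 %*% t(u1) + sqrt(r2_sex) * z2 %*% t(u2) +
    sqrt(1 - r2_size - r2_sex) * E
  list(y = y, data = tibble(size = size, sex = factor(sex, levels = c("F", "M"))))
}
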