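test_that("centroid size has the closed form and is homogeneous", {
  cube <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5)))
  expect_equal(centroid_size(cube), sqrt(6), tolerance = 1e-12)
  expect_equal(centroid_size(matrix(2, 5, 3)), 0)
  X <- toy_config()
  s <- 3.7
  expect_equal(centroid_size(X * s), s * centroid_size(X), tolerance = 1e-12)
  expect_error(centroid_size(matrix(numeric(0), 0, 3)), "empty")
})

test_that("OPA recovers rigid motions exactly and never reflects", {
  X <- toy_config()
  self <- opa_align(X, X)
  expect_equal(self$residual, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  Y <- random_rigid_copy(X, seed = 42)
  fit <- opa_align(Y, X)
  expect_lt(fit$residual, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # mirrored copy cannot be recovered with a proper rotation
  Xm <- X
  Xm[, 1] <- -Xm[, 1]
  fitm <- opa_align(Xm, X)
  expect_gt(fitm$residual, 1e-3)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-12)
})

test_that("OPA residual matches a brute-force search over proper rotations", {
  X <- toy_config()
  Xm <- X
  Xm[, 1] <- -Xm[, 1]  # reflected: strictly positive residual
  expect_equal(opa_align(Xm, X)$residual, opa_oracle(Xm, X), tolerance = 1e-6)

  set.seed(9)
  Z <- X + matrix(rnorm(15, 0, 0.3), 5, 3)
  expect_equal(opa_align(Z, X)$residual, opa_oracle(Z, X), tolerance = 1e-6)
})

test_that("optimal OPA scaling reduces the residual for resized copies", {
  X <- toy_config()
  Y <- random_rigid_copy(X, seed = 3, scale = 2.5)
  expect_lt(opa_align(Y, X, scale = TRUE)$residual, 1e-9)
  expect_gt(opa_align(Y, X, scale = FALSE)$residual, 0.1)
})

test_that("GPA aligns rigid copies of one shape to zero Procrustes distance", {
  s <- tiny_set(n = 8)
  fit <- gpa(s, scale = TRUE)
  expect_lte(max(procrustes_dist(fit)), 1e-8)
  # all equal the consensus
  for (i in 1:8) {
    expect_equal(fit$aligned[, , i], fit$consensus, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("GPA invariants: centered at origin, unit size when scaled, consensus = mean", {
  s <- simulate_landmarks(n_f = 5, n_m = 5, n_points = 40, noise_sd = 1, seed = 2)
  fit <- gpa(s, scale = TRUE)
  for (i in seq_len(dim(fit$aligned)[3])) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-9)
    expect_equal(centroid_size(fit$aligned[, , i]), 1, tolerance = 1e-9)
  }
  expect_equal(fit$consensus, apply(fit$aligned, c(1, 2), mean),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(fit$final_change, 1e-10)
  # original sizes stored regardless of scaling
  expect_true(all(fit$csize > 100))
})

test_that("GPA matches a naive alternating-optimization oracle on small triangles", {
  set.seed(5)
  arr <- array(NA_real_, c(4, 3, 3))
  for (i in 1:3) {
    tri <- cbind(matrix(rnorm(8), 4, 2), 0)   # planar quadrilateral
    arr[, , i] <- random_rigid_copy(tri, seed = 20 + i)
  }
  dimnames(arr) <- list(paste0("p", 1:4), c("x", "y", "z"), paste0("s", 1:3))
  fit <- gpa(arr, scale = TRUE, tol = 1e-14, max_iter = 1000)
  ora <- gpa_oracle(arr, scale = TRUE)
  expect_equal(fit$consensus, ora$consensus, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$aligned, ora$aligned, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("GPA output is invariant to rigid pre-transformation of any specimen", {
  s <- simulate_landmarks(n_f = 4, n_m = 4, n_points = 40, noise_sd = 1, seed = 3)
  fit1 <- gpa(s)
  arr <- landmark_array(s)
  arr[, , 2] <- random_rigid_copy(arr[, , 2], seed = 77, scale = 1.9)
  s2 <- as_specimen_set(arr, specimens = specimen_info(s), points = point_info(s))
  fit2 <- gpa(s2)
  expect_equal(fit1$aligned, fit2$aligned, tolerance = 1e-8)
})

test_that("degenerate specimens are rejected with an informative error", {
  arr <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
  arr[, , 2] <- cbind(1:5, 2 * (1:5), -(1:5))  # collinear
  expect_error(gpa(arr), "specimen 2")
})

test_that("symmetrize is a fixed point on symmetric shapes and idempotent", {
  base <- make_base_shape(60, seed = 4)
  arr <- array(rep(base$coordinates, 2), c(nrow(base$coordinates), 3, 2),
               dimnames = list(rownames(base$coordinates), c("x", "y", "z"),
                               c("a", "b")))
  s <- as_specimen_set(arr, points = base$points)
  sym <- symmetrize(s)
  expect_equal(landmark_array(sym), landmark_array(s), tolerance = 1e-9)

  # noisy configurations: idempotence and zero reflect-relabel residual
  s2 <- simulate_landmarks(n_f = 2, n_m = 2, n_points = 60, noise_sd = 1, seed = 5)
  sym1 <- symmetrize(s2)
  sym2 <- symmetrize(sym1)
  expect_equal(landmark_array(sym1), landmark_array(sym2), tolerance = 1e-8)
  pm <- morphosignal:::pairs_matrix(sym1)
  for (i in 1:4) {
    expect_lt(morphosignal:::reflect_relabel_residual(landmark_array(sym1)[, , i], pm),
              1e-8)
  }
})

test_that("symmetrize moves a displaced point halfway back toward its mirror image", {
  # on a large configuration, displacing one paired point barely rotates the
  # reflected copy in the superimposition, so the symmetrized position is the
  # midpoint between the displaced point and its mirrored partner
  b <- make_base_shape(100, seed = 30)
  X <- b$coordinates
  pm_tbl <- b$points
  i_left <- which(pm_tbl$side == "L" & pm_tbl$pair == 5L)
  delta <- c(0, 0.05, 0)
  Xd <- X
  Xd[i_left, ] <- Xd[i_left, ] + delta
  arr <- array(Xd, c(nrow(X), 3, 1),
               dimnames = list(pm_tbl$point_id, c("x", "y", "z"), "a"))
  s <- as_specimen_set(arr, points = pm_tbl)
  sym <- landmark_array(symmetrize(s))[, , 1]
  pm <- morphosignal:::pairs_matrix(s)
  expect_lt(morphosignal:::reflect_relabel_residual(sym, pm), 1e-9)
  # hand computation: the pristine mirror partner pulls the average halfway
  expect_lt(max(abs((sym[i_left, ] - X[i_left, ]) - delta / 2)), 0.005)
  # untouched points barely move
  others <- setdiff(seq_len(nrow(X)), c(i_left, pm[pm[, 1] == i_left, 2],
                                        pm[pm[, 2] == i_left, 1]))
  expect_lt(max(abs(sym[others, ] - X[others, ])), 0.01)
})

test_that("symmetrize requires a pairing scheme", {
  s <- tiny_set(4)
  expect_error(symmetrize(s), "pairs")
})
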