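test_that("noiseless allometric data give R^2 = 1 and exact coefficient recovery", {
  b <- make_base_shape(40, seed = 2)
  k <- nrow(b$coordinates)
  av <- allometry_vectors(k, 0, seed = 1)
  s <- simulate_landmarks(n_f = 30, n_m = 30, n_points = 40,
                          size_mean = c(f = 975, m = 975),
                          allometry = av, allometry_strength = 0.1,
                          noise_sd = 0, seed = 2)
  fit <- gpa(s)
  mod <- allometric_regression(fit, groups = rep("all", 60), log_predictor = TRUE)
  # Procrustes renormalization leaves a vanishing nonlinearity
  expect_equal(mod$fits$all$r_squared, 1, tolerance = 1e-4)
  # recovered direction parallels the planted field after carrying it into
  # the consensus frame and removing what superimposition absorbs (the
  # size direction and the infinitesimal rigid motions of the base shape)
  B <- attr(s, "ground_truth")$base_shape
  R <- opa_align(B, fit$consensus, scale = TRUE)$rotation
  Br <- B %*% R
  k <- nrow(B)
  skew <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
               rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  G <- cbind(as.vector(Br),
             sapply(skew, function(a) as.vector(Br %*% a)),
             kronecker(diag(3), rep(1, k)))
  Q <- qr.Q(qr(G))
  v <- as.vector(av$f %*% R)
  v_perp <- v - Q %*% crossprod(Q, v)
  beta <- mod$fits$all$coefficients
  cosang <- abs(sum(beta * v_perp)) / sqrt(sum(beta^2) * sum(v_perp^2))
  expect_gt(cosang, 0.99)
})

test_that("size-independent shapes give near-zero R^2", {
  r2 <- replicate(20, NA_real_)
  for (i in 1:20) {
    s <- simulate_landmarks(n_f = 50, n_m = 50, n_points = 30,
                            size_mean = c(f = 975, m = 975),
                            noise_sd = 1.5, seed = 100 + i)
    fit <- gpa(s)
    r2[i] <- allometric_regression(fit, groups = rep("all", 100))$fits$all$r_squared
  }
  # null R^2 of a single predictor is ~ 1/(n-1); allow generous slack
  expect_lt(mean(r2), 3 / (100 - 1))
})

test_that("coefficients match a per-variable least-squares oracle", {
  s <- simulate_landmarks(n_f = 20, n_m = 20, n_points = 30, noise_sd = 1, seed = 3)
  fit <- gpa(s)
  mod <- allometric_regression(fit, log_predictor = FALSE)
  y <- morphosignal:::flatten_configs(fit$aligned)
  x <- fit$csize
  sex <- specimen_info(s)$sex
  for (g in c("F", "M")) {
    rows <- which(sex == g)
    beta_oracle <- vapply(seq_len(ncol(y)), function(j) {
      unname(coef(lm(y[rows, j] ~ x[rows]))[2])
    }, numeric(1))
    expect_equal(mod$fits[[g]]$coefficients, beta_oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # predicted extreme shapes have the configuration's dimensions
  f <- mod$fits$F
  expect_equal(dim(f$predicted_min_shape), c(dim(s)[1], 3L))
})

test_that("trajectory angle has the right closed-form values", {
  expect_equal(trajectory_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(trajectory_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(trajectory_angle(c(1, 1, 0), c(-1, -1, 0)), 180)
  # planted rotation in a 3-variable space
  v1 <- c(1, 0, 0)
  a <- 25 * pi / 180
  v2 <- c(cos(a), sin(a), 0)
  expect_equal(trajectory_angle(v1, v2), 25, tolerance = 1e-9)
  expect_equal(trajectory_angle(v2, v1), 25, tolerance = 1e-9)  # symmetric
  expect_error(trajectory_angle(c(0, 0, 0), v1), "zero-norm")
})

test_that("a planted trajectory divergence is detected by the permutation test", {
  k <- nrow(make_base_shape(40, seed = 5)$coordinates)
  av <- allometry_vectors(k, 60, seed = 4)
  s <- simulate_landmarks(n_f = 40, n_m = 40, n_points = 40,
                          size_mean = c(f = 975, m = 975),
                          size_sdlog = c(f = 0.06, m = 0.06),
                          allometry = av, allometry_strength = 0.15,
                          noise_sd = 0.05, seed = 5)
  fit <- gpa(s)
  res <- angle_permutation_test(fit, n_perm = 99, seed = 6, log_predictor = TRUE)
  expect_equal(res$angle, 60, tolerance = 6)
  expect_lte(res$p_value, 0.01)
})

test_that("the permutation p-value is in (0, 1] and reproducible", {
  s <- simulate_landmarks(n_f = 15, n_m = 15, n_points = 30, noise_sd = 1, seed = 7)
  fit <- gpa(s)
  r1 <- angle_permutation_test(fit, n_perm = 49, seed = 8)
  r2 <- angle_permutation_test(fit, n_perm = 49, seed = 8)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})
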