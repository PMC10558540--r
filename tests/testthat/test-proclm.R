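test_that("an exact linear response gives the size term all the variance", {
  set.seed(1)
  n <- 30
  size <- rnorm(n)
  beta <- rnorm(6)
  y <- outer(size, beta)  # exactly linear, zero noise
  data <- tibble::tibble(size = size, sex = factor(rep(c("F", "M"), n / 2)))
  res <- procrustes_lm(y, data, ~ size + sex, n_perm = 99, seed = 1)
  expect_equal(res$fraction[res$term == "size"], 1, tolerance = 1e-9)
  expect_equal(res$p_value[res$term == "size"], 1 / 100)
})

test_that("fractions over terms plus residual sum to one", {
  set.seed(2)
  n <- 40
  data <- tibble::tibble(size = rnorm(n), sex = factor(rep(c("F", "M"), n / 2)))
  y <- matrix(rnorm(n * 10), n, 10) + outer(data$size, rnorm(10, 0, 0.5))
  res <- procrustes_lm(y, data, ~ size + sex + size:sex, n_perm = 49, seed = 3)
  expect_equal(sum(res$fraction), 1, tolerance = 1e-9)
  expect_true(all(res$fraction >= -1e-12))
})

test_that("a term unrelated to the response gets a small fraction and flat p", {
  set.seed(3)
  n <- 60
  data <- tibble::tibble(size = rnorm(n), sex = factor(rep(c("F", "M"), n / 2)))
  y <- matrix(rnorm(n * 20), n, 20)
  res <- procrustes_lm(y, data, ~ size + sex, n_perm = 199, seed = 4)
  # null expectation of a 1-df fraction is ~ 1/(n-1)
  expect_lt(res$fraction[res$term == "sex"], 5 / (n - 1))
  expect_gt(res$p_value[res$term == "sex"], 0.01)
})

test_that("planted variance fractions are recovered", {
  sim <- simulate_variance_partition(n = 200, n_vars = 60,
                                     r2_size = 0.4, r2_sex = 0.1, seed = 5)
  res <- procrustes_lm(sim$y, sim$data, ~ size + sex + size:sex,
                       n_perm = 99, seed = 6)
  expect_equal(res$fraction[res$term == "size"], 0.4, tolerance = 0.05)
  expect_equal(res$fraction[res$term == "sex"], 0.1, tolerance = 0.05)
  expect_lt(res$p_value[res$term == "size"], 0.05)
  expect_lt(res$p_value[res$term == "sex"], 0.05)
  expect_gt(res$p_value[res$term == "size:sex"], 0.05)
})

test_that("sequential fractions agree with an independent permutational MANOVA", {
  skip_if_not_installed("vegan")
  set.seed(7)
  n <- 24
  data <- data.frame(size = rnorm(n), sex = factor(rep(c("F", "M"), n / 2)))
  y <- matrix(rnorm(n * 8), n, 8) + outer(data$size, rnorm(8)) +
    outer(as.numeric(data$sex) - 1.5, rnorm(8, 0, 0.6))
  res <- procrustes_lm(y, data, ~ size + sex, n_perm = 49, seed = 8)
  veg <- vegan::adonis2(dist(y) ~ size + sex, data = data, permutations = 49,
                        by = "terms")
  expect_equal(res$fraction[1:2], veg$R2[1:2], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rank-deficient designs are rejected", {
  n <- 20
  data <- tibble::tibble(size = rnorm(n), size2 = NA)
  data$size2 <- data$size * 2
  y <- matrix(rnorm(n * 4), n, 4)
  expect_error(procrustes_lm(y, data, ~ size + size2, n_perm = 9), "rank-deficient")
})

test_that("repeatability is 100% for perfect replicates and ~0% for pure noise", {
  s <- simulate_landmarks(n_f = 4, n_m = 4, n_points = 40, noise_sd = 0,
                          individual_sd = 2, n_replicates = 3, seed = 9)
  expect_equal(repeatability(s)$repeatability, 100, tolerance = 1e-6)

  s0 <- simulate_landmarks(n_f = 4, n_m = 4, n_points = 40, noise_sd = 1.5,
                           individual_sd = 0, n_replicates = 3,
                           size_sdlog = c(f = 0, m = 0), seed = 10)
  expect_lt(repeatability(s0)$repeatability, 20)
})

test_that("repeatability recovers a planted variance ratio and matches an ANOVA oracle", {
  # direct shape-variable check against per-variable variance components
  set.seed(11)
  a <- 8; r <- 4; p <- 12
  ind_eff <- matrix(rnorm(a * p, 0, 3), a, p)
  y <- ind_eff[rep(1:a, each = r), ] + matrix(rnorm(a * r * p, 0, 1), a * r, p)
  ids <- rep(sprintf("i%d", 1:a), each = r)
  res <- repeatability(y, individuals = ids)

  # oracle: pooled one-way ANOVA mean squares via stats::aov per variable
  ms_a <- ms_w <- 0
  for (j in 1:p) {
    av <- summary(stats::aov(y[, j] ~ factor(ids)))[[1]]
    ms_a <- ms_a + av$`Sum Sq`[1]
    ms_w <- ms_w + av$`Sum Sq`[2]
  }
  ms_a <- ms_a / (a - 1); ms_w <- ms_w / (a * (r - 1))
  oracle <- 100 * (ms_a - ms_w) / (ms_a + (r - 1) * ms_w)
  expect_equal(res$repeatability, oracle, tolerance = 1e-9)
  # planted 9:1 ratio -> intraclass expectation 90%
  expect_equal(res$repeatability, 90, tolerance = 5)
})

test_that("unbalanced replicate designs are rejected", {
  y <- matrix(rnorm(5 * 3), 5, 3)
  expect_error(repeatability(y, individuals = c("a", "a", "b", "b", "b")),
               "unbalanced")
})
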