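# Unit-scale mapping checks run on small configurations and few permutations;
# full study-scale calibration lives in test-acceptance.R.

null_set <- function(seed = 1, n = 20, pts = 40) {
  simulate_landmarks(n_f = n, n_m = n, n_points = pts,
                     size_mean = c(f = 975, m = 975), noise_sd = 1,
                     seed = seed)
}

test_that("a null dataset maps to chance-level accuracy everywhere", {
  s <- null_set()
  m <- map_signal(s, "shape", k = 10, n_perm = 30, seed = 2)
  expect_true(all(m$acc_total > 0.25 & m$acc_total < 0.75))
  expect_lt(abs(mean(m$acc_total) - 0.5), 0.05)
  expect_true(all(m$n_perm_ok == 30))
})

test_that("a planted localized effect is recovered by the shape map", {
  b <- make_base_shape(80, seed = 1)
  d <- as.matrix(dist(b$coordinates))
  patch <- order(d[25, ])[1:10]
  spacing_mm <- b$mean_spacing / centroid_size(b$coordinates) * 975
  s <- simulate_landmarks(n_f = 30, n_m = 30, n_points = 80,
                          size_mean = c(f = 975, m = 975),
                          effect_indices = patch,
                          effect_size = 6 * 1 / spacing_mm, noise_sd = 1,
                          seed = 3)
  m <- map_signal(s, "shape", k = 10, n_perm = 30, seed = 4)
  gap <- mean(m$acc_total[patch]) - mean(m$acc_total[-patch])
  expect_gt(gap, 0.2)
  expect_true(which.max(m$acc_total) %in% patch)
})

test_that("size dimorphism with no shape effect elevates the size-only map uniformly", {
  s <- simulate_landmarks(n_f = 30, n_m = 30, n_points = 40,
                          size_mean = c(f = 900, m = 1050),
                          size_sdlog = c(f = 0.02, m = 0.02),
                          noise_sd = 0.5, seed = 5)
  m <- map_signal(s, "size", k = 10, n_perm = 30, seed = 6)
  expect_true(all(m$acc_total > 0.8))
  expect_lt(sd(m$acc_total), 0.05)
})

test_that("per-point totals equal the test-count-weighted class accuracies", {
  s <- null_set(seed = 7, n = 13, pts = 30)  # unequal test counts by class
  m <- map_signal(s, "shape", k = 8, n_perm = 10, seed = 8)
  counts <- attr(m, "n_test")
  weighted <- (counts[1] * m$acc_f + counts[2] * m$acc_m) / sum(counts)
  expect_equal(m$acc_total, weighted, tolerance = 1e-12)
})

test_that("maps are invariant to global rigid motion and rescaling of the sample", {
  s <- null_set(seed = 9, n = 12, pts = 30)
  m0 <- map_signal(s, "shape", k = 8, n_perm = 8, seed = 10)

  arr <- landmark_array(s)
  set.seed(123)
  R <- morphosignal:::random_rotation()
  for (i in seq_len(dim(arr)[3])) {
    arr[, , i] <- arr[, , i] %*% R + matrix(c(5, -3, 8), dim(arr)[1], 3, byrow = TRUE)
  }
  s_rot <- as_specimen_set(arr, specimens = specimen_info(s), points = point_info(s))
  m_rot <- map_signal(s_rot, "shape", k = 8, n_perm = 8, seed = 10)
  expect_equal(m0$acc_total, m_rot$acc_total, tolerance = 1e-12)

  # shape space: also invariant to global rescaling
  s_scl <- as_specimen_set(arr * 1.7, specimens = specimen_info(s),
                           points = point_info(s))
  m_scl <- map_signal(s_scl, "shape", k = 8, n_perm = 8, seed = 10)
  expect_equal(m0$acc_total, m_scl$acc_total, tolerance = 1e-12)
})

test_that("form and size maps are invariant to a common rescaling of all specimens", {
  s <- null_set(seed = 11, n = 12, pts = 30)
  arr <- landmark_array(s) * 2.3  # shifts every log-size by log(2.3)
  s_scl <- as_specimen_set(arr, specimens = specimen_info(s), points = point_info(s))
  for (space in c("form", "size")) {
    m0 <- map_signal(s, space, k = 8, n_perm = 8, seed = 12)
    m1 <- map_signal(s_scl, space, k = 8, n_perm = 8, seed = 12)
    expect_equal(m0$acc_total, m1$acc_total, tolerance = 1e-12)
  }
})

test_that("maps do not depend on specimen storage order", {
  s <- null_set(seed = 13, n = 12, pts = 30)
  m0 <- map_signal(s, "shape", k = 8, n_perm = 8, seed = 14)
  set.seed(99)
  perm <- sample(dim(s)[3])
  s_perm <- filter_specimens(s, perm)
  m1 <- map_signal(s_perm, "shape", k = 8, n_perm = 8, seed = 14)
  expect_equal(m0$acc_total, m1$acc_total, tolerance = 1e-12)
})

test_that("mapping requires complete sex labels and names offenders", {
  s <- null_set(seed = 15, n = 6, pts = 30)
  meta <- specimen_info(s)
  meta$sex[3] <- NA
  s2 <- as_specimen_set(landmark_array(s), specimens = meta, points = point_info(s))
  expect_error(map_signal(s2, "shape", n_perm = 2), meta$specimen_id[3])
})

test_that("a module covering the whole shape is consistent with whole-shape LDA", {
  s <- simulate_landmarks(n_f = 25, n_m = 25, n_points = 40,
                          size_mean = c(f = 975, m = 975),
                          effect_indices = 1:40, effect_size = 0.15,
                          noise_sd = 0.8, seed = 16)
  res_mod <- combined_module_accuracy(s, list(1:40), space = "shape",
                                      n_perm = 100, seed = 17)
  fit <- gpa(s)
  res_lda <- lda_accuracy(shape_matrix(fit), specimen_info(s)$sex,
                          n_perm = 100, seed = 17)
  expect_equal(res_mod$acc_total, res_lda$acc_total, tolerance = 0.1)
  expect_gt(res_mod$acc_total, 0.8)
})

test_that("a pure-noise module classifies at chance", {
  # averaged over independent null datasets (one dataset's cross-validated
  # accuracy keeps an O(1/sqrt(n)) dataset-level wobble around chance)
  accs <- vapply(1:5, function(i) {
    s <- null_set(seed = 300 + i, n = 25, pts = 30)
    combined_module_accuracy(s, list(5:14), space = "shape",
                             n_perm = 60, seed = 19)$acc_total
  }, numeric(1))
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})

test_that("pooling two planted patches is at least as informative as either alone", {
  b <- make_base_shape(60, seed = 20)
  d <- as.matrix(dist(b$coordinates))
  p1 <- order(d[10, ])[1:6]
  p2 <- order(d[50, ])[1:6]
  skip_if(length(intersect(p1, p2)) > 0)
  spacing_mm <- b$mean_spacing / centroid_size(b$coordinates) * 975
  delta <- numeric(10)
  for (i in 1:10) {
    s <- simulate_landmarks(n_f = 20, n_m = 20, n_points = 60,
                            size_mean = c(f = 975, m = 975),
                            effect_indices = c(p1, p2),
                            effect_size = 3 / spacing_mm, noise_sd = 1,
                            seed = 200 + i)
    a1 <- combined_module_accuracy(s, list(p1), "shape", n_perm = 30, seed = 21)$acc_total
    a2 <- combined_module_accuracy(s, list(p2), "shape", n_perm = 30, seed = 21)$acc_total
    au <- combined_module_accuracy(s, list(p1, p2), "shape", n_perm = 30, seed = 21)$acc_total
    delta[i] <- au - max(a1, a2)
  }
  expect_gt(mean(delta), -0.02)  # statistical tendency, not per-replicate
})

test_that("map comparison behaves like a correlation with a quantile subset", {
  s <- null_set(seed = 22, n = 12, pts = 30)
  m <- map_signal(s, "shape", k = 8, n_perm = 10, seed = 23)
  self <- compare_maps(m, m)
  expect_equal(self$r, 1, tolerance = 1e-12)

  m_inv <- m
  m_inv$acc_total <- 1 - m$acc_total
  inv <- compare_maps(m, m_inv)
  expect_equal(inv$r, -1, tolerance = 1e-12)

  sub <- compare_maps(m, m, subset_quantile = 0.75)
  expect_equal(sub$subset_r, 1, tolerance = 1e-12)
  expect_equal(sub$subset_cutoff,
               unname(quantile(m$acc_total, 0.75, type = 7)), tolerance = 1e-12)
  expect_lte(sub$subset_n, nrow(m))

  m_const <- m
  m_const$acc_total <- rep(0.5, nrow(m))
  expect_true(is.na(compare_maps(m_const, m)$r))
})

test_that("split-half maps of a planted signal correlate positively", {
  b <- make_base_shape(60, seed = 24)
  d <- as.matrix(dist(b$coordinates))
  patch <- order(d[15, ])[1:8]
  spacing_mm <- b$mean_spacing / centroid_size(b$coordinates) * 975
  s <- simulate_landmarks(n_f = 40, n_m = 40, n_points = 60,
                          size_mean = c(f = 975, m = 975),
                          effect_indices = patch, effect_size = 5 / spacing_mm,
                          noise_sd = 1, seed = 25)
  ids <- specimen_info(s)$specimen_id
  half1 <- filter_specimens(s, ids[c(1:20, 41:60)])
  half2 <- filter_specimens(s, ids[c(21:40, 61:80)])
  m1 <- map_signal(half1, "shape", k = 8, n_perm = 25, seed = 26)
  m2 <- map_signal(half2, "shape", k = 8, n_perm = 25, seed = 27)
  res <- compare_maps(m1, m2)
  expect_gt(res$r, 0.3)
  expect_lt(res$p_value, 0.01)
})
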