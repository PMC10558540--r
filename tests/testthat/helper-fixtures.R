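# Small in-code fixtures shared across test files.

# a rigid 5-point non-degenerate 3D configuration
toy_config <- function() {
  matrix(c(
    0, 0, 0,
    1, 0, 0,
    0, 1, 0,
    0, 0, 1,
    1, 1, 1
  ), ncol = 3, byrow = TRUE)
}

random_rigid_copy <- function(X, seed, scale = 1) {
  set.seed(seed)
  R <- morphosignal:::random_rotation()
  scale * X %*% R + matrix(rnorm(3, 0, 5), nrow(X), 3, byrow = TRUE)
}

# tiny specimen set: n rigid copies of one shape plus per-copy noise
tiny_set <- function(n = 6, noise = 0, seed = 1, base = NULL) {
  X <- if (is.null(base)) toy_config() else base
  k <- nrow(X)
  arr <- array(NA_real_, c(k, 3, n),
               dimnames = list(paste0("p", 1:k), c("x", "y", "z"),
                               sprintf("s%02d", 1:n)))
  for (i in 1:n) {
    Y <- random_rigid_copy(X, seed + i)
    if (noise > 0) {
      set.seed(seed + 1000 + i)
      Y <- Y + matrix(rnorm(3 * k, 0, noise), k, 3)
    }
    arr[, , i] <- Y
  }
  as_specimen_set(arr, specimens = tibble::tibble(
    specimen_id = dimnames(arr)[[3]],
    sex = rep(c("F", "M"), length.out = n)
  ))
}

# brute-force OPA oracle: optimize over the 3 Euler angles of a proper
# rotation (plus analytic translation) to minimize summed squared distance
opa_oracle <- function(X, ref, n_starts = 40, seed = 1) {
  Xc <- sweep(X, 2, colMeans(X))
  Rc <- sweep(ref, 2, colMeans(ref))
  euler <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(a) sum((Xc %*% euler(a) - Rc)^2)
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    a0 <- runif(3, -pi, pi)
    o <- stats::optim(a0, obj, method = "BFGS", control = list(maxit = 500))
    if (o$value < best) best <- o$value
  }
  sqrt(best)
}

# brute-force alternating-optimization GPA oracle (plain R, no shortcuts)
gpa_oracle <- function(arr, scale = TRUE, iters = 200) {
  n <- dim(arr)[3]
  A <- arr
  for (i in 1:n) {
    Xi <- sweep(A[, , i], 2, colMeans(A[, , i]))
    if (scale) Xi <- Xi / sqrt(sum(Xi^2))
    A[, , i] <- Xi
  }
  cons <- apply(A, c(1, 2), mean)
  cons <- sweep(cons, 2, colMeans(cons))
  if (scale) cons <- cons / sqrt(sum(cons^2))
  for (it in 1:iters) {
    for (i in 1:n) {
      sv <- svd(crossprod(A[, , i], cons))
      R <- sv$u %*% t(sv$v)
      if (det(R) < 0) {
        u <- sv$u; u[, 3] <- -u[, 3]
        R <- u %*% t(sv$v)
      }
      A[, , i] <- A[, , i] %*% R
    }
    newcons <- apply(A, c(1, 2), mean)
    newcons <- sweep(newcons, 2, colMeans(newcons))
    if (scale) newcons <- newcons / sqrt(sum(newcons^2))
    if (max(abs(newcons - cons)) < 1e-14) { cons <- newcons; break }
    cons <- newcons
  }
  # same canonical frame convention as the implementation: principal axes of
  # the consensus, signs from the largest-|coordinate| rule, det +1
  final <- apply(A, c(1, 2), mean)
  V <- svd(final)$v
  sc <- final %*% V
  for (j in 1:3) if (sc[which.max(abs(sc[, j])), j] < 0) V[, j] <- -V[, j]
  if (det(V) < 0) V[, 3] <- -V[, 3]
  for (i in 1:n) A[, , i] <- A[, , i] %*% V
  list(aligned = A, consensus = apply(A, c(1, 2), mean))
}
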