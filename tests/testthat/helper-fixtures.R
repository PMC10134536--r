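# shared fixture builders; all randomness is locally seeded

make_gaussian <- function(n, p, seed = 1, beta = NULL, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- rnorm(p, 0, 0.3)
  y <- drop(x %*% beta) + rnorm(n, 0, sd)
  list(data = codapen_data(x, y, "gaussian"), beta = beta)
}

make_binomial <- function(n, p, seed = 1, beta = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- rnorm(p, 0, 0.5)
  y <- rbinom(n, 1, 1 / (1 + exp(-drop(x %*% beta))))
  list(data = codapen_data(x, y, "binomial"), beta = beta)
}

# independent de Boor recursion, written directly from the recurrence
deboor_basis <- function(z, knots, degree) {
  nb <- length(knots) - degree - 1L
  b <- sapply(seq_len(length(knots) - 1L), function(j)
    as.numeric(z >= knots[j] & z < knots[j + 1L]))
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  for (d in seq_len(degree)) {
    bn <- matrix(0, length(z), length(knots) - d - 1L)
    for (j in seq_len(ncol(bn))) {
      den1 <- knots[j + d] - knots[j]
      den2 <- knots[j + d + 1L] - knots[j + 1L]
      t1 <- if (den1 > 0) (z - knots[j]) / den1 * b[, j] else 0
      t2 <- if (den2 > 0) (knots[j + d + 1L] - z) / den2 * b[, j + 1L] else 0
      bn[, j] <- t1 + t2
    }
    b <- bn
  }
  b[, seq_len(nb), drop = FALSE]
}

# dense p x p reference for the moment-system quantities
dense_moment_reference <- function(x, w, omega, z) {
  m <- crossprod(x, x * w)
  minv <- solve(m + omega * diag(ncol(x)))
  cmat <- minv %*% m
  list(a = (cmat * cmat) %*% z, v_tilde = diag(cmat %*% minv))
}

random_moment_instance <- function(seed, n, p, G) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p), w = runif(n, 0.5, 2),
       omega = runif(1, 0.5, 3), beta_tilde = rnorm(p),
       z = matrix(rnorm(p * G), p, G))
}
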