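test_that("orthonormal moment system matches its closed form", {
  d <- codapen_data(diag(3), c(2, 0, 2), "gaussian")
  sys <- build_moment_system(d, rep(1, 3), 1, beta_tilde = c(1, 0, 1),
                             z = matrix(1, 3, 1), block_size = 2)
  expect_equal(drop(sys$a), rep(0.25, 3))
  expect_equal(sys$v_tilde, rep(0.25, 3))
  expect_equal(sys$b, c(0.75, -0.25, 0.75))
})

test_that("blockwise computation equals the dense p-by-p reference for all block sizes", {
  inst <- random_moment_instance(8, n = 15, p = 40, G = 3)
  d <- codapen_data(inst$x, rnorm(15), "gaussian")
  ref <- dense_moment_reference(inst$x, inst$w, inst$omega, inst$z)
  for (bs in c(1, 7, 40)) {
    sys <- build_moment_system(d, inst$w, inst$omega, inst$beta_tilde,
                               z = inst$z, block_size = bs)
    expect_lt(max(abs(sys$a - ref$a)), 1e-10)
    expect_lt(max(abs(sys$v_tilde - ref$v_tilde)), 1e-10)
  }
})

test_that("global scale solves the one-group system and truncates at zero", {
  d <- codapen_data(diag(3), c(2, 0, 2), "gaussian")
  tau2 <- estimate_global_tau(d, 1, w = rep(1, 3), beta_tilde = c(1, 0, 1))
  expect_equal(tau2, 5 / 3, tolerance = 1e-12)

  # b <= 0 everywhere: beta_tilde = 0 makes b = -v_tilde <= 0
  tau0 <- estimate_global_tau(d, 1, w = rep(1, 3), beta_tilde = rep(0, 3))
  expect_equal(tau0, 0)
})

test_that("global scale recovers a constant prior variance under the generative model", {
  n <- 100; p <- 300; v_true <- 0.1
  taus <- vapply(1:20, function(r) {
    set.seed(100 + r)
    beta0 <- rnorm(p, 0, sqrt(v_true))
    x <- matrix(rnorm(n * p), n, p)
    y <- drop(x %*% beta0) + rnorm(n)
    d <- codapen_data(x, y, "gaussian")
    set.seed(r)
    lam <- cv_constant_ridge(d)$lambda
    estimate_global_tau(d, lam)
  }, numeric(1))
  expect_lt(abs(mean(taus) - v_true) / v_true, 0.3)
})

test_that("linear co-data solve truncates and matches the normal equations", {
  # orthonormal instance: moment_design is I/4, so with Z = I2 and
  # beta_tilde = (2, 0) the solve gives gamma = 4 b = (15, -1) and the
  # negative fitted variance is truncated to zero
  d <- codapen_data(diag(2), c(1, 1), "gaussian")
  sys <- build_moment_system(d, rep(1, 2), 1, c(2, 0))
  sol <- solve_linear_codata(sys, diag(2))
  expect_equal(sol$gamma, c(15, -1), tolerance = 1e-10)
  expect_equal(sol$v, c(15, 0), tolerance = 1e-10)

  inst <- random_moment_instance(5, n = 12, p = 30, G = 4)
  d2 <- codapen_data(inst$x, rnorm(12), "gaussian")
  sys2 <- build_moment_system(d2, inst$w, inst$omega, inst$beta_tilde)
  a <- moment_design(sys2, inst$z)
  sol2 <- solve_linear_codata(sys2, inst$z)
  oracle <- solve(crossprod(a), crossprod(a, sys2$b))
  expect_lt(max(abs(sol2$gamma - drop(oracle))), 1e-8)

  # consistent system reproduces its generator
  g0 <- c(0.5, -1, 2, 0.3)
  sys2$b <- drop(a %*% g0)
  sol3 <- solve_linear_codata(sys2, inst$z)
  expect_lt(max(abs(sol3$gamma - g0)), 1e-8)
})

test_that("gam solve matches the penalised normal equations and its degeneracies", {
  set.seed(6)
  p <- 120; n <- 25
  x <- matrix(rnorm(n * p), n, p)
  z <- runif(p)
  d <- codapen_data(x, rnorm(n), "gaussian")
  sys <- build_moment_system(d, runif(n, 0.5, 2), 1.5, rnorm(p, 0, 0.2))
  phi <- z_spline_basis(z, 10, 3)
  s <- difference_penalty(10, 2)

  # zero penalty equals the linear solve on the expanded design
  g0 <- solve_gam_codata(sys, phi, s, 0)
  glin <- solve_linear_codata(sys, phi)
  expect_lt(max(abs(g0$gamma - glin$gamma)), 1e-8)

  # penalised least-squares oracle, single block (non-singular system)
  sol1 <- solve_gam_codata(sys, phi, s, 2)
  oracle1 <- solve(crossprod(moment_design(sys, phi)) + 2 * s,
                   crossprod(moment_design(sys, phi), sys$b))
  expect_lt(max(abs(sol1$gamma - drop(oracle1))), 1e-8)

  # two blocks share the constant direction (both bases are partitions of
  # unity annihilated by the difference penalties), so the coefficient
  # system is rank-deficient; the fitted prior variances are still unique
  # and must match an independent min-norm solve of the augmented system
  phi2 <- cbind(phi, z_spline_basis(z^2, 8, 3))
  s2 <- list(s, difference_penalty(8, 2))
  blocks <- list(1:10, 11:18)
  sol <- suppressWarnings(solve_gam_codata(sys, phi2, s2, c(2, 5), blocks))
  a <- moment_design(sys, phi2)
  pen <- matrix(0, 18, 18)
  pen[1:10, 1:10] <- 2 * s; pen[11:18, 11:18] <- 5 * s2[[2]]
  ev <- eigen(pen, symmetric = TRUE)
  root <- sqrt(pmax(ev$values, 0)) * t(ev$vectors)
  aug <- rbind(a, root)
  rhs <- c(sys$b, numeric(nrow(root)))
  sv <- svd(aug)
  keep <- sv$d > 1e-10 * max(sv$d)
  oracle2 <- sv$v %*% (ifelse(keep, 1 / sv$d, 0) * crossprod(sv$u, rhs))
  expect_lt(max(abs(drop(phi2 %*% sol$gamma) - drop(phi2 %*% oracle2))),
            1e-8)

  # heavy smoothing with a second-order penalty forces an affine curve
  gi <- solve_gam_codata(sys, phi, s, 1e10)
  grid <- seq(min(z), max(z), length.out = 100)
  cur <- drop(eval_spline_basis(phi, grid) %*% gi$gamma)
  res <- residuals(lm(cur ~ grid))
  expect_lt(max(abs(res)) / diff(range(cur)), 1e-4)
})

test_that("random-splits smoothing penalty agrees with a grid oracle and is deterministic", {
  set.seed(9)
  p <- 150; n <- 40
  z <- runif(p)
  phi <- z_spline_basis(z, 10, 3)
  s <- difference_penalty(10, 2)
  # a response whose moment right-hand side is linear in the co-data
  beta_lin <- rnorm(p, 0, sqrt(0.02 + 0.25 * z))
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% beta_lin) + rnorm(n)
  d <- codapen_data(x, y, "gaussian")
  builder <- function(idx) {
    sub <- codapen_data(d$x[idx, , drop = FALSE], d$y[idx], "gaussian")
    codapen:::initial_moment_system(sub, 30, intercept = FALSE)
  }
  lam <- estimate_smoothing_penalty(builder, n, phi, s, n_splits = 5,
                                    seed = 42)
  lam2 <- estimate_smoothing_penalty(builder, n, phi, s, n_splits = 5,
                                     seed = 42)
  expect_identical(lam, lam2)
  # linear truth prefers heavy smoothing: upper half of the search range
  expect_gt(log10(lam), 0)

  # grid oracle: Brent's minimiser within one log10 grid cell of the
  # 17-point grid minimum
  splits <- local({
    set.seed(42)
    lapply(1:5, function(i) {
      tr <- sort(sample.int(n, n %/% 2))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })
  })
  score <- function(l10) {
    mean(vapply(splits, function(sp) {
      st <- builder(sp$train); se <- builder(sp$test)
      at <- moment_design(st, phi); ae <- moment_design(se, phi)
      g <- solve(crossprod(at) + 10^l10 * s, crossprod(at, st$b))
      sum((ae %*% g - se$b)^2)
    }, numeric(1)))
  }
  grid <- seq(-8, 8, by = 1)
  best <- grid[which.min(vapply(grid, score, numeric(1)))]
  expect_lte(abs(log10(lam) - best), 1)

  # strong high-frequency structure prefers less smoothing than the
  # linear truth
  beta_hf <- rnorm(p, 0, sqrt(0.02 + 0.3 * (sin(12 * z) + 1)))
  y_hf <- drop(x %*% beta_hf) + rnorm(n, 0, 0.2)
  d_hf <- codapen_data(x, y_hf, "gaussian")
  builder_hf <- function(idx) {
    sub <- codapen_data(d_hf$x[idx, , drop = FALSE], d_hf$y[idx],
                        "gaussian")
    codapen:::initial_moment_system(sub, 30, intercept = FALSE)
  }
  lam_hf <- estimate_smoothing_penalty(builder_hf, n, phi, s,
                                       n_splits = 5, seed = 42)
  expect_lt(lam_hf, lam)
})

test_that("shape-constrained solve honours constraints and optimality", {
  set.seed(12)
  p <- 100; n <- 25; J <- 5
  z <- runif(p)
  x <- matrix(rnorm(n * p), n, p)
  d <- codapen_data(x, rnorm(n), "gaussian")
  sys <- build_moment_system(d, rep(1, n), 1, rnorm(p, 0, 0.3))
  phi <- z_spline_basis(z, J, 2)
  s <- difference_penalty(J, 2)

  # inactive constraints reproduce the unconstrained penalised solve:
  # bound everything far away from the optimum
  con_wide <- list(m_ineq = rbind(diag(J), -diag(J)),
                   b_ineq = rep(1e6, 2 * J),
                   m_eq = matrix(0, 0, J), b_eq = numeric(0))
  sol_c <- solve_scam_codata(sys, phi, s, 2, con_wide)
  sol_g <- solve_gam_codata(sys, phi, s, 2)
  expect_lt(max(abs(sol_c$gamma - sol_g$gamma)), 1e-6)

  # all-negative signal under positivity collapses to the zero vector
  sys_neg <- sys
  sys_neg$b <- -abs(sys$b) - 0.1
  pos <- shape_constraints("positive", J)
  sol0 <- solve_scam_codata(sys_neg, phi, s, 1, pos)
  expect_lt(max(abs(sol0$gamma)), 1e-8)

  # optimality against random feasible points (monotone increasing)
  mono <- shape_constraints("monotone_increasing", J)
  sol_m <- solve_scam_codata(sys, phi, s, 1, mono)
  a <- moment_design(sys, phi)
  obj <- function(g) sum((a %*% g - sys$b)^2) + drop(g %*% s %*% g)
  o_star <- obj(sol_m$gamma)
  set.seed(99)
  worse <- replicate(10000, {
    g <- cumsum(abs(rnorm(J, 0, 0.3))) + rnorm(1, 0, 0.5)  # increasing
    obj(g)
  })
  expect_true(all(o_star <= worse + 1e-8))
  expect_true(all(mono$m_ineq %*% sol_m$gamma <= 1e-8))

  # infeasible systems are reported as such
  infeas <- list(m_ineq = rbind(c(1, rep(0, J - 1)), c(-1, rep(0, J - 1))),
                 b_ineq = c(-1, -1), m_eq = matrix(0, 0, J),
                 b_eq = numeric(0))
  expect_error(solve_scam_codata(sys, phi, s, 1, infeas), "infeasible")
})

test_that("source weights solve non-negative least squares", {
  set.seed(14)
  p <- 60; n <- 20
  x <- matrix(rnorm(n * p), n, p)
  d <- codapen_data(x, rnorm(n), "gaussian")
  sys <- build_moment_system(d, rep(1, n), 1, rnorm(p, 0, 0.3))

  # D = 1: scalar non-negative least squares
  c1 <- abs(rnorm(p))
  a1 <- drop(moment_design(sys, c1))
  w1 <- estimate_source_weights(list(c1), sys)
  expect_gte(w1, 0)
  expect_equal(w1, max(sum(a1 * sys$b) / sum(a1^2), 0), tolerance = 1e-12)

  # D = 2 where contribution 1 generates b exactly: brute-force grid
  # oracle should land on w = (1, 0)
  c2 <- abs(rnorm(p))
  a2 <- drop(moment_design(sys, c2))
  sys2 <- sys
  sys2$b <- a1               # so w = (1, 0) reproduces b exactly
  w <- estimate_source_weights(list(c1, c2), sys2)
  grid <- seq(0, 2, by = 0.01)
  obj <- outer(grid, grid, Vectorize(function(w1g, w2g)
    sum((w1g * a1 + w2g * a2 - sys2$b)^2)))
  best <- arrayInd(which.min(obj), dim(obj))
  expect_lt(abs(w[1] - grid[best[1]]), 0.02)
  expect_lt(abs(w[2] - grid[best[2]]), 0.02)

  # b = 0 gives zero weights
  sys0 <- sys
  sys0$b <- rep(0, p)
  expect_equal(estimate_source_weights(list(c1, c2), sys0), c(0, 0))

  # rescaling a contribution by c > 0 is compensated by 1/c in w
  w_base <- estimate_source_weights(list(c1, c2), sys)
  w_scaled <- estimate_source_weights(list(c1 * 10, c2), sys)
  expect_equal(w_scaled[1] * 10, w_base[1], tolerance = 1e-6)
  expect_equal(w_scaled[2], w_base[2], tolerance = 1e-6)
})

test_that("moment consistency: mean of b over replicates approaches A gamma0", {
  # gaussian family with known unit weights; X, omega fixed so the
  # sampling-variance term is computed once
  set.seed(31)
  n <- 100; p <- 200
  z <- cbind(1, runif(p))
  gamma0 <- c(0.02, 0.1)
  v0 <- drop(z %*% gamma0)
  x <- matrix(rnorm(n * p), n, p)
  omega <- 1 / mean(v0)
  d0 <- codapen_data(x, rnorm(n), "gaussian")
  sys <- build_moment_system(d0, rep(1, n), omega, rnorm(p))
  minv_xt <- solve(crossprod(x) + omega * diag(p), t(x))
  bsum <- 0
  nrep <- 100
  for (r in 1:nrep) {
    set.seed(400 + r)
    beta0 <- rnorm(p, 0, sqrt(v0))
    y <- drop(x %*% beta0) + rnorm(n)
    bsum <- bsum + drop(minv_xt %*% y)^2 - sys$v_tilde
  }
  # compare through the moment functional the estimator actually solves:
  # the co-data projection of mean(b) must recover gamma0 (the raw
  # p-vector of squared estimates carries an irreducible sqrt(2/nrep)
  # chi-square noise floor)
  a <- moment_design(sys, z)
  gam_hat <- drop(solve(crossprod(a), crossprod(a, bsum / nrep)))
  expect_lt(sqrt(sum((gam_hat - gamma0)^2)) / sqrt(sum(gamma0^2)), 0.15)
})
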