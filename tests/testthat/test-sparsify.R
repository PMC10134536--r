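test_that("variance function has its closed forms at the endpoints", {
  expect_equal(variance_function(2, alpha = 0), 0.5)
  expect_equal(variance_function(1, alpha = 1), 2)
  # Laplace variance computed directly from its density
  lam <- 1.7
  v_laplace <- integrate(function(b) b^2 * (lam / 2) * exp(-lam * abs(b)),
                         -Inf, Inf)$value
  expect_equal(variance_function(lam, alpha = 1), v_laplace,
               tolerance = 1e-8)
})

test_that("variance function is strictly decreasing and below each pure-component variance", {
  lam <- 10^seq(-2, 2, length.out = 25)
  for (al in c(0.3, 0.5, 0.7)) {
    h <- variance_function(lam, al)
    expect_true(all(h > 0))
    expect_true(all(diff(h) < 0))
    # the elastic-net density is the (renormalised) product of a Laplace
    # and a gaussian factor, hence more concentrated than either alone
    ub <- pmin(1 / (lam * (1 - al)), 2 / (lam * al)^2)
    expect_true(all(h <= ub * (1 + 1e-9)))
  }
})

test_that("quadrature agrees with an independent direct-density oracle", {
  for (al in c(0.25, 0.5, 0.8)) {
    for (lam in c(0.3, 2, 20)) {
      dens <- function(b) exp(-lam * (al * abs(b) + (1 - al) * b^2 / 2))
      m0 <- integrate(dens, -40, 40, rel.tol = 1e-12)$value
      m2 <- integrate(function(b) b^2 * dens(b), -40, 40,
                      rel.tol = 1e-12)$value
      expect_equal(variance_function(lam, al), m2 / m0, tolerance = 1e-9)
    }
  }
})

test_that("penalty transform inverts the variance function", {
  expect_equal(transform_penalties(c(0.5, 0.25), alpha = 0), c(2, 4))
  expect_equal(transform_penalties(2, alpha = 1), 1)
  set.seed(8)
  v <- 10^runif(20, -3, 1)
  lam <- transform_penalties(v, alpha = 0.3)
  expect_lt(max(abs(variance_function(lam, 0.3) - v)), 1e-6)
  expect_error(transform_penalties(c(1, 0), 0.5), "positive")
  expect_error(variance_function(-1, 0.5), "positive")
})

test_that("alpha = 0 coordinate descent matches the ridge fit", {
  g <- make_gaussian(30, 20, seed = 41)
  pen <- runif(20, 0.5, 5)
  en <- fit_adaptive_elastic_net(g$data, pen, alpha = 0)
  rg <- fit_weighted_ridge(g$data, pen)
  expect_lt(max(abs(en$eta - rg$eta)), 1e-5)
})

test_that("huge penalties zero their coefficients exactly and objectives never increase", {
  g <- make_gaussian(40, 15, seed = 43)
  pen <- rep(1, 15); pen[c(2, 9, 14)] <- 1e8
  en <- fit_adaptive_elastic_net(g$data, pen, alpha = 0.8)
  expect_identical(en$beta[c(2, 9, 14)], c(0, 0, 0))
  expect_true(all(diff(en$objective) <= 1e-9))

  b <- make_binomial(50, 10, seed = 44)
  enb <- fit_adaptive_elastic_net(b$data, rep(2, 10), alpha = 0.5)
  expect_true(enb$converged)
})

test_that("lasso on an orthonormal design equals soft thresholding", {
  set.seed(45)
  q <- qr.Q(qr(matrix(rnorm(30 * 8), 30, 8)))   # orthonormal columns
  beta0 <- c(2, -1.5, 0, 0.8, 0, 0, 3, -0.2)
  y <- drop(q %*% beta0) + rnorm(30, 0, 0.3)
  d <- codapen_data(q, y, "gaussian")
  lam <- c(0.1, 0.5, 1, 0.2, 2, 0.05, 0.4, 0.3)
  en <- fit_adaptive_elastic_net(d, lam, alpha = 1, intercept = FALSE)
  bols <- drop(crossprod(q, y))
  oracle <- sign(bols) * pmax(abs(bols) - lam, 0)
  expect_equal(en$beta, oracle, tolerance = 1e-10)
})

test_that("uniform elastic net matches glmnet under the penalty-scale mapping", {
  skip_if_not_installed("glmnet")
  g <- make_gaussian(40, 12, seed = 47)
  lam_gl <- 0.08
  al <- 0.5
  # glmnet objective is (1/2n)||y - b0 - Xb||^2 + lam (al |b| + (1-al) b^2/2)
  en <- fit_adaptive_elastic_net(g$data, rep(g$data$n * lam_gl, 12),
                                 alpha = al)
  gl <- glmnet::glmnet(g$data$x, g$data$y, alpha = al, lambda = lam_gl,
                       standardize = FALSE, thresh = 1e-12)
  bg <- drop(as.matrix(gl$beta))
  expect_equal(en$beta, bg, tolerance = 0.05, ignore_attr = TRUE)
  # same objective, and our solution is at least as good an optimiser
  obj <- function(b, b0) {
    0.5 * sum((g$data$y - b0 - g$data$x %*% b)^2) +
      g$data$n * lam_gl * sum(al * abs(b) + (1 - al) * b^2 / 2)
  }
  expect_lte(obj(en$beta, en$intercept), obj(bg, gl$a0) + 1e-6)
})

test_that("variable selection reports non-zero indices with count and alpha", {
  g <- make_gaussian(20, 4, seed = 49)
  en <- fit_adaptive_elastic_net(g$data, rep(1, 4), alpha = 0.5)
  en$beta <- c(0, 1.2, 0, -0.3)
  sel <- select_variables(en)
  expect_equal(sel$index, c(2L, 4L))
  expect_equal(sel$count, 2L)
  expect_equal(sel$alpha, 0.5)
  en$beta <- rep(0, 4)
  expect_length(select_variables(en)$index, 0)
})

test_that("selected-set size trends downward as alpha grows at fixed penalties", {
  g <- make_gaussian(60, 40, seed = 51,
                     beta = c(rnorm(10, 0, 0.8), rep(0, 30)))
  counts <- sapply(c(0.1, 0.5, 0.9), function(al) {
    en <- suppressWarnings(
      fit_adaptive_elastic_net(g$data, rep(8, 40), alpha = al))
    sum(en$beta != 0)
  })
  expect_true(counts[3] <= counts[1])
})
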