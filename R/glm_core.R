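# Penalised GLM / Cox core: IRLS with variable-specific ridge penalties.
#
# Conventions: the gaussian likelihood is taken on the unit-variance scale,
# so the objective is -0.5*||y - eta||^2 - 0.5*sum(penalty_k * beta_k^2);
# the noise variance enters later through the IRLS weights (1/sigma^2).
# The intercept is never penalised: gaussian/binomial profile it out by
# (weighted) centring inside each IRLS step, cox has none.

#' Fit a ridge-penalised GLM or Cox model with per-variable penalties
#'
#' Maximises the family log-likelihood minus \eqn{\frac{1}{2}\sum_k
#' \lambda_k \beta_k^2} by iteratively reweighted least squares (Newton for
#' Cox, with Breslow tie handling), with step halving so the penalised
#' log-likelihood is non-decreasing across iterations.  When `p > n` and all
#' penalties are positive the weighted least-squares step is solved through
#' the n-by-n dual system, which is algebraically identical to the primal
#' normal equations.
#'
#' @param data A [codapen_data()] object.
#' @param penalties Length-`p` non-negative ridge penalty vector, or a
#'   scalar recycled to length `p`.
#' @param intercept Include an unpenalised intercept?  Ignored (forced off)
#'   for the cox family.
#' @param tol Relative L-infinity convergence tolerance on the coefficients.
#' @param max_iter Iteration cap; non-convergence raises a warning and is
#'   flagged in the returned object.
#' @return A `codapen_ridge` object: `beta` (length `p`), `intercept`
#'   (`NA` for cox), `eta` (training linear predictor), `penalties`,
#'   `family`, `converged`, `iterations`, `loglik` (penalised log-likelihood
#'   trace) and, for gaussian, `sigma2` (residual variance estimate,
#'   residual sum of squares over `n` minus the effective degrees of
#'   freedom).
#' @examples
#' set.seed(1)
#' d <- codapen_data(matrix(rnorm(40), 10, 4), rnorm(10), "gaussian")
#' fit <- fit_weighted_ridge(d, penalties = 1)
#' @export
fit_weighted_ridge <- function(data, penalties, intercept = TRUE,
                               tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "codapen_data"))
  p <- data$p
  n <- data$n
  if (length(penalties) == 1L) penalties <- rep(penalties, p)
  if (length(penalties) != p) stop("penalties must have length p")
  if (any(!is.finite(penalties)) || any(penalties < 0))
    stop("penalties must be finite and non-negative")
  if (p > n && all(penalties == 0))
    stop("singular system: p > n requires at least one positive penalty")

  fam <- data$family
  fit <- switch(fam$name,
    gaussian = ridge_fit_gaussian(data, penalties, intercept),
    binomial = ridge_fit_binomial(data, penalties, intercept, tol, max_iter),
    cox      = ridge_fit_cox(data, penalties, tol, max_iter)
  )
  fit$penalties <- penalties
  fit$family <- fam
  fit$n <- n
  fit$p <- p
  class(fit) <- "codapen_ridge"
  fit
}

# Solve (Xc' W Xc + diag(pen)) beta = Xc' W z for already-centred Xc, z.
# Dual (Woodbury) route when p > n and all penalties positive.
solve_ridge_wls <- function(xc, z, w, penalties) {
  n <- nrow(xc)
  p <- ncol(xc)
  if (p > n && all(penalties > 0)) {
    xs <- sweep(xc, 2L, penalties, "/")          # X diag(pen)^-1
    k <- tcrossprod(xs, xc)                      # X pen^-1 X'
    diag(k) <- diag(k) + 1 / w
    sol <- tryCatch(solve(k, z), error = function(e)
      stop("singular dual system: ", conditionMessage(e)))
    drop(crossprod(xs, sol))
  } else {
    a <- crossprod(xc, xc * w)
    diag(a) <- diag(a) + penalties
    tryCatch(drop(solve(a, crossprod(xc, w * z))), error = function(e)
      stop("singular ridge system (condition estimate ",
           format(tryCatch(kappa(a), error = function(e2) NA)),
           "): ", conditionMessage(e)))
  }
}

ridge_fit_gaussian <- function(data, penalties, intercept) {
  x <- data$x; y <- data$y; n <- data$n; p <- data$p
  if (intercept) {
    xm <- colMeans(x); ym <- mean(y)
    xc <- sweep(x, 2L, xm)
    beta <- solve_ridge_wls(xc, y - ym, rep(1, n), penalties)
    b0 <- ym - sum(xm * beta)
  } else {
    beta <- solve_ridge_wls(x, y, rep(1, n), penalties)
    b0 <- 0
  }
  eta <- drop(x %*% beta) + b0
  resid <- y - eta
  # effective dof of the linear smoother (hat-matrix trace), + 1 if intercept
  xc <- if (intercept) sweep(x, 2L, colMeans(x)) else x
  df <- ridge_edf(xc, penalties) + as.numeric(intercept)
  sigma2 <- sum(resid^2) / max(n - df, 1)
  pll <- -0.5 * sum(resid^2) - 0.5 * sum(penalties * beta^2)
  list(beta = beta, intercept = if (intercept) b0 else 0, eta = eta,
       converged = TRUE, iterations = 1L, loglik = pll,
       sigma2 = sigma2, edf = df)
}

# trace of X (X'X + diag(pen))^-1 X' without forming p x p when p > n
ridge_edf <- function(x, penalties) {
  n <- nrow(x); p <- ncol(x)
  if (p > n && all(penalties > 0)) {
    xs <- sweep(x, 2L, penalties, "/")
    k <- tcrossprod(xs, x)                    # K = X pen^-1 X'
    diag(k) <- diag(k) + 1
    n - sum(diag(solve(k)))                   # tr(K (K+I)^-1) = n - tr((K+I)^-1)
  } else {
    a <- crossprod(x)
    diag(a) <- diag(a) + penalties
    h <- tryCatch(solve(a, crossprod(x)), error = function(e) NULL)
    if (is.null(h)) return(min(n, p))
    sum(diag(h))
  }
}

binomial_pll <- function(y, eta, penalties, beta) {
  sum(y * eta - log1p(exp(eta))) - 0.5 * sum(penalties * beta^2)
}

ridge_fit_binomial <- function(data, penalties, intercept, tol, max_iter) {
  x <- data$x; y <- data$y; n <- data$n; p <- data$p
  beta <- rep(0, p)
  b0 <- if (intercept) response_family("binomial")$link(
    min(max(mean(y), 1e-3), 1 - 1e-3)) else 0
  eta <- rep(b0, n)
  ll_trace <- binomial_pll(y, eta, penalties, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    if (intercept) {
      wm <- sum(w)
      xm <- colSums(x * w) / wm
      zm <- sum(z * w) / wm
      xc <- sweep(x, 2L, xm)
      beta_new <- solve_ridge_wls(xc, z - zm, w, penalties)
      b0_new <- zm - sum(xm * beta_new)
    } else {
      beta_new <- solve_ridge_wls(x, z, w, penalties)
      b0_new <- 0
    }
    # step halving: keep the penalised log-likelihood non-decreasing
    step <- 1
    repeat {
      bs <- beta + step * (beta_new - beta)
      b0s <- b0 + step * (b0_new - b0)
      etas <- drop(x %*% bs) + b0s
      lls <- binomial_pll(y, etas, penalties, bs)
      if (lls >= ll_trace[iter] - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    delta <- max(abs(bs - beta), abs(b0s - b0))
    scale <- max(1, abs(bs), abs(b0s))
    beta <- bs; b0 <- b0s; eta <- etas
    ll_trace <- c(ll_trace, lls)
    if (delta / scale < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations",
            call. = FALSE)
  list(beta = beta, intercept = b0, eta = eta, converged = converged,
       iterations = iter, loglik = ll_trace)
}

# Breslow partial-likelihood pieces: for each distinct event time j with
# d_j events and risk-set exp-eta sum S_j, ll = sum_events eta_i -
# sum_j d_j log S_j.  Gradient/curvature in eta follow from pi_ij =
# exp(eta_i) 1(i in R_j) / S_j.
cox_parts <- function(time, event, eta) {
  n <- length(time)
  ord <- order(time)
  et <- unique(time[ord][event[ord] == 1])
  J <- length(et)
  ex <- exp(eta)
  risk <- outer(time, et, ">=")               # n x J risk-set membership
  s <- colSums(risk * ex)                     # S_j
  d <- vapply(et, function(t) sum(event == 1 & time == t), numeric(1))
  pi_ <- sweep(risk * ex, 2L, s, "/")         # pi_ij
  grad <- event - drop(pi_ %*% d)
  wdiag <- drop(pi_ %*% d) - drop((pi_^2) %*% d)
  ll <- sum(eta[event == 1]) - sum(d * log(s))
  list(ll = ll, grad = grad, wdiag = wdiag, pi_ = pi_, d = d)
}

cox_hessian_eta <- function(parts) {
  # A = diag(sum_j d_j pi_ij) - P diag(d) P'
  diag(drop(parts$pi_ %*% parts$d)) - parts$pi_ %*% (parts$d * t(parts$pi_))
}

ridge_fit_cox <- function(data, penalties, tol, max_iter) {
  x <- data$x; n <- data$n; p <- data$p
  time <- data$y[, 1L]; event <- data$y[, 2L]
  beta <- rep(0, p)
  eta <- rep(0, n)
  parts <- cox_parts(time, event, eta)
  ll_trace <- parts$ll - 0.5 * sum(penalties * beta^2)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- cox_hessian_eta(parts)
    h <- crossprod(x, a %*% x)
    diag(h) <- diag(h) + penalties + 1e-12
    g <- drop(crossprod(x, parts$grad)) - penalties * beta
    dir <- tryCatch(drop(solve(h, g)), error = function(e)
      stop("singular cox information: ", conditionMessage(e)))
    step <- 1
    repeat {
      bs <- beta + step * dir
      etas <- drop(x %*% bs)
      ps <- cox_parts(time, event, etas)
      lls <- ps$ll - 0.5 * sum(penalties * bs^2)
      if (lls >= ll_trace[iter] - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    delta <- max(abs(bs - beta))
    scale <- max(1, abs(bs))
    beta <- bs; eta <- etas; parts <- ps
    ll_trace <- c(ll_trace, lls)
    if (delta / scale < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Cox Newton iterations did not converge in ", max_iter,
            " iterations", call. = FALSE)
  list(beta = beta, intercept = NA_real_, eta = eta, converged = converged,
       iterations = iter, loglik = ll_trace)
}

#' IRLS weight diagonal at a fitted model
#'
#' Returns the diagonal of the weight matrix `W` of the iteratively
#' reweighted least-squares algorithm evaluated at the fit: constant
#' \eqn{1/\hat\sigma^2} for gaussian, \eqn{\hat p_i(1-\hat p_i)} for
#' binomial (floored at 1e-10 with a warning if any fitted probability is
#' degenerate), and the diagonal of the observed information of the Breslow
#' partial likelihood for cox.
#'
#' @param fit A `codapen_ridge` fit.
#' @param data The [codapen_data()] it was fitted on.
#' @return Positive length-`n` vector.
#' @export
irls_weights <- function(fit, data) {
  stopifnot(inherits(fit, "codapen_ridge"))
  switch(fit$family$name,
    gaussian = rep(1 / fit$sigma2, data$n),
    binomial = {
      mu <- 1 / (1 + exp(-fit$eta))
      w <- mu * (1 - mu)
      if (any(w < 1e-10)) {
        warning("fitted probabilities numerically 0/1; weights floored",
                call. = FALSE)
        w <- pmax(w, 1e-10)
      }
      w
    },
    cox = {
      parts <- cox_parts(data$y[, 1L], data$y[, 2L], fit$eta)
      pmax(parts$wdiag, 1e-10)
    }
  )
}

#' Predict from a fitted penalised model
#'
#' Returns \eqn{g^{-1}(X_{new}\beta + intercept)} on the response scale;
#' for cox the linear predictor (log relative hazard) is returned.
#'
#' @param object A `codapen_ridge` (or `codapen_enet`) fit.
#' @param xnew Matrix with `p` columns.
#' @param ... Unused.
#' @export
predict_response <- function(object, xnew, ...) {
  xnew <- as.matrix(xnew)
  if (ncol(xnew) != length(object$beta))
    stop(sprintf("xnew has %d columns but the model has %d coefficients",
                 ncol(xnew), length(object$beta)))
  b0 <- if (is.na(object$intercept)) 0 else object$intercept
  eta <- drop(xnew %*% object$beta) + b0
  if (object$family$name == "binomial") 1 / (1 + exp(-eta)) else eta
}

#' @export
predict.codapen_ridge <- function(object, xnew, ...) predict_response(object, xnew)

#' @export
print.codapen_ridge <- function(x, ...) {
  cat("<codapen_ridge>", x$family$name, "fit:", x$p, "variables,",
      x$n, "samples;", sum(x$beta != 0), "non-zero coefficients\n")
  invisible(x)
}
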