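# Empirical Bayes moment estimation of co-data coefficients.
#
# Given an initial constant-ridge fit (beta_tilde, IRLS weights W, ridge
# level omega), the marginal second moments of beta_tilde satisfy, under
# the normal prior with variances v = Z gamma,
#     (C o C) Z gamma = beta_tilde^2 - v_tilde =: b,
# with C = (X'WX + omega I)^-1 X'WX and v_tilde the sampling variance of
# beta_tilde.  C is p x p but factors as C = U' K^-1 U with U = W^{1/2} X
# and K = U U' + omega I (n x n), so (C o C) Z and diag terms are computed
# per block of rows without ever materialising C.

#' Build the moment system of the empirical Bayes estimator
#'
#' Computes the design \eqn{A=(C\circ C)Z}, the right-hand side
#' \eqn{b=\tilde\beta^{.2}-\tilde v}, and the sampling-variance estimate
#' \eqn{\tilde v}, blockwise in `block_size` rows of `C`, holding at most
#' an `block_size`-by-`p` slice of `C` in memory.  The returned object
#' retains the n-by-p factor so the same transformed design can be reused
#' for spline expansions and source contributions.
#'
#' @param data A [codapen_data()] object (only `x` is used).
#' @param w Length-n positive IRLS weight diagonal.
#' @param omega_tilde Initial constant ridge penalty on the weighted scale
#'   (must be positive).
#' @param beta_tilde Length-p initial ridge estimate.
#' @param z Optional p-by-G co-data matrix for which `A` is cached.
#' @param block_size Rows of `C` processed per block (default 500).
#' @return A `moment_system`: `a` (p-by-G, if `z` given), `b`, `v_tilde`,
#'   `beta_tilde`, `omega_tilde`, `w`, and internal factors.
#' @export
build_moment_system <- function(data, w, omega_tilde, beta_tilde,
                                z = NULL, block_size = 500L) {
  stopifnot(block_size >= 1L, omega_tilde > 0)
  x <- data$x
  n <- nrow(x); p <- ncol(x)
  if (length(w) != n) stop("w must have length n")
  if (length(beta_tilde) != p) stop("beta_tilde must have length p")
  u <- x * sqrt(w)                              # W^{1/2} X
  k <- tcrossprod(u)
  diag(k) <- diag(k) + omega_tilde
  kinv_u <- tryCatch(solve(k, u), error = function(e)
    stop("singular inner n-by-n system (condition number ~ ",
         format(tryCatch(kappa(k), error = function(e2) NA), digits = 3),
         "): ", conditionMessage(e)))
  sys <- structure(list(u = u, kinv_u = kinv_u, omega_tilde = omega_tilde,
                        beta_tilde = beta_tilde, w = w, n = n, p = p,
                        block_size = as.integer(block_size)),
                   class = "moment_system")
  # v_tilde = (diag(C) - diag(C C)) / omega, blockwise
  vt <- numeric(p)
  a <- if (!is.null(z)) matrix(0, p, ncol(as.matrix(z))) else NULL
  z <- if (!is.null(z)) as.matrix(z) else NULL
  for (idx in block_indices(p, block_size)) {
    cb <- crossprod(u[, idx, drop = FALSE], kinv_u)   # block rows of C
    dc <- cb[cbind(seq_along(idx), idx)]              # diag(C)[idx]
    vt[idx] <- (dc - rowSums(cb^2)) / omega_tilde
    if (!is.null(z)) a[idx, ] <- (cb * cb) %*% z
  }
  sys$v_tilde <- pmax(vt, 0)
  sys$b <- beta_tilde^2 - sys$v_tilde
  sys$a <- a
  sys
}

block_indices <- function(p, block_size) {
  starts <- seq(1L, p, by = block_size)
  lapply(starts, function(s) s:min(s + block_size - 1L, p))
}

#' Transformed design for an arbitrary variable-level matrix
#'
#' Computes \eqn{(C\circ C)\,M} blockwise for any p-row matrix `M`
#' (a co-data matrix, a spline expansion, or a source contribution).
#'
#' @param sys A `moment_system`.
#' @param m p-by-q matrix or length-p vector.
#' @export
moment_design <- function(sys, m) {
  m <- as.matrix(m)
  if (nrow(m) != sys$p) stop("m must have p rows")
  out <- matrix(0, sys$p, ncol(m))
  for (idx in block_indices(sys$p, sys$block_size)) {
    cb <- crossprod(sys$u[, idx, drop = FALSE], sys$kinv_u)
    out[idx, ] <- (cb * cb) %*% m
  }
  out
}

#' @export
print.moment_system <- function(x, ...) {
  cat("<moment_system> p =", x$p, ", n =", x$n,
      ", omega =", format(x$omega_tilde), "\n")
  invisible(x)
}

#' Estimate the global prior-variance scale
#'
#' Solves the moment system for the degenerate co-data of a single
#' all-ones column (one group containing all variables) in least squares
#' and truncates at zero.  Under a constant prior variance this recovers
#' that variance; in the full pipeline it serves as the global scaling
#' estimate.
#'
#' @param data A [codapen_data()] object.
#' @param omega_init Initial constant ridge penalty (natural likelihood
#'   scale, as in [fit_weighted_ridge()]).
#' @param w,beta_tilde Optional overrides for the IRLS weights and initial
#'   estimate; computed from a constant-ridge fit when `NULL`.
#' @param intercept Use an intercept in the initial fit.
#' @return Scalar `tau2 >= 0`.
#' @export
estimate_global_tau <- function(data, omega_init, w = NULL,
                                beta_tilde = NULL, intercept = TRUE) {
  stopifnot(omega_init > 0)
  sys <- initial_moment_system(data, omega_init, w, beta_tilde, intercept)
  solve_scalar_ls(drop(moment_design(sys, rep(1, data$p))), sys$b)
}

solve_scalar_ls <- function(a, b) {
  if (all(b == 0)) {
    warning("moment right-hand side identically zero: no prior signal",
            call. = FALSE)
    return(0)
  }
  max(sum(a * b) / sum(a * a), 0)
}

# Shared plumbing: initial constant-ridge fit -> weights -> moment system.
# For gaussian the natural-scale penalty omega_init corresponds to
# omega_tilde = omega_init / sigma^2 on the weighted (W = I/sigma^2) scale.
initial_moment_system <- function(data, omega_init, w = NULL,
                                  beta_tilde = NULL, intercept = TRUE,
                                  z = NULL, block_size = 500L) {
  if (is.null(w) || is.null(beta_tilde)) {
    use_int <- intercept && data$family$name != "cox"
    fit <- fit_weighted_ridge(data, omega_init, intercept = use_int)
    if (is.null(w)) w <- irls_weights(fit, data)
    if (is.null(beta_tilde)) beta_tilde <- fit$beta
    omega_tilde <- if (data$family$name == "gaussian")
      omega_init / fit$sigma2 else omega_init
    dat <- if (use_int) center_data(data, w) else data
  } else {
    omega_tilde <- omega_init
    dat <- data
  }
  build_moment_system(dat, w, omega_tilde, beta_tilde, z = z,
                      block_size = block_size)
}

# weighted centring of X: the unpenalised intercept is profiled out of the
# moment equations, matching its treatment in the IRLS steps
center_data <- function(data, w) {
  xm <- colSums(data$x * w) / sum(w)
  out <- data
  out$x <- sweep(data$x, 2L, xm)
  out
}

#' Solve the linear co-data model
#'
#' Least-squares solve of the moment system for a linear co-data model,
#' with elementwise truncation of the fitted prior variances at zero.
#' Rank-deficient designs fall back to the minimum-norm solution with a
#' warning.
#'
#' @param sys A `moment_system`.
#' @param z p-by-G co-data matrix.
#' @return List: `gamma` (length G), `v` (length p, `(Z gamma)+`), `a`.
#' @export
solve_linear_codata <- function(sys, z) {
  z <- as.matrix(z)
  a <- moment_design(sys, z)
  gamma <- lstsq_minnorm(a, sys$b)
  list(gamma = gamma, v = pmax(drop(z %*% gamma), 0), a = a)
}

# solve a symmetric PSD system, falling back to the pseudoinverse when it
# is numerically singular (e.g. boundary spline coefficients with no
# co-data support at near-zero smoothing)
solve_or_pinv <- function(h, g) {
  tryCatch(drop(solve(h, g)), error = function(e) {
    ev <- eigen(h, symmetric = TRUE)
    keep <- ev$values > 1e-12 * max(ev$values, .Machine$double.eps)
    drop(ev$vectors %*% (ifelse(keep, 1 / ev$values, 0) *
                           crossprod(ev$vectors, g)))
  })
}

lstsq_minnorm <- function(a, b, tol = 1e-10) {
  sv <- svd(a)
  keep <- sv$d > tol * max(sv$d, .Machine$double.eps)
  if (!all(keep))
    warning("rank-deficient moment design; returning minimum-norm solution",
            call. = FALSE)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * crossprod(sv$u, b)))
}

#' Solve the generalised additive co-data model
#'
#' Penalised least squares on the spline-expanded moment system: minimises
#' \eqn{\|A_{GAM}\gamma-b\|_2^2+\sum_g\lambda_g\gamma_g^\top S_g\gamma_g}
#' through the penalised normal equations, then truncates the fitted prior
#' variances at zero.
#'
#' @param sys A `moment_system`.
#' @param phi p-by-J stacked spline expansion \eqn{[\Phi_1,...,\Phi_G]}.
#' @param s_list List of per-variable difference penalty matrices.
#' @param lambda_list Non-negative smoothing penalties, one per block.
#' @param blocks List of column index vectors of `phi` per co-data
#'   variable; a single block covering all columns when `NULL`.
#' @return List: `gamma`, `v`, `a`.
#' @export
solve_gam_codata <- function(sys, phi, s_list, lambda_list, blocks = NULL) {
  phi <- as.matrix(phi)
  if (is.null(blocks)) blocks <- list(seq_len(ncol(phi)))
  if (!is.list(s_list)) s_list <- list(s_list)
  lambda_list <- as.numeric(lambda_list)
  if (any(lambda_list < 0)) stop("smoothing penalties must be >= 0")
  a <- moment_design(sys, phi)
  pen <- matrix(0, ncol(phi), ncol(phi))
  for (g in seq_along(blocks))
    pen[blocks[[g]], blocks[[g]]] <- lambda_list[g] * s_list[[g]]
  h <- crossprod(a) + pen
  gamma <- tryCatch(drop(solve(h, crossprod(a, sys$b))),
                    error = function(e) lstsq_minnorm_pen(a, sys$b, pen))
  list(gamma = gamma, v = pmax(drop(phi %*% gamma), 0), a = a)
}

lstsq_minnorm_pen <- function(a, b, pen) {
  # augmented least squares [A; pen^{1/2}] gamma ~ [b; 0], minimum norm
  rt <- mat_sqrt_psd(pen)
  lstsq_minnorm(rbind(a, rt), c(b, numeric(nrow(rt))))
}

mat_sqrt_psd <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  (sqrt(vals) * t(e$vectors))
}

#' Estimate a smoothing penalty by random sample splits
#'
#' For each random half/half split of the samples, the spline coefficients
#' are fitted on the training half's moment system at candidate penalty
#' `lambda` and scored by the residual of the held-out half's moment
#' system; the split-averaged score is minimised over
#' \eqn{\log_{10}\lambda \in [-8, 8]} with Brent's method.
#'
#' @param sys_builder Function taking a vector of sample indices and
#'   returning a `moment_system` for that subset.
#' @param n Total number of samples to split.
#' @param phi,s Spline expansion (p-by-J) and difference penalty (J-by-J).
#' @param n_splits Number of random splits (default 10).
#' @param seed Integer seed making the splits reproducible.
#' @return Selected `lambda >= 0` (scalar).
#' @export
estimate_smoothing_penalty <- function(sys_builder, n, phi, s,
                                       n_splits = 10L, seed = 1L) {
  stopifnot(n_splits >= 1L)
  if (n < 4L) stop("too few samples to split")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  half <- floor(n / 2)
  if (half < 2L) stop("degenerate split: fewer than 2 samples per half")
  splits <- lapply(seq_len(n_splits), function(i) {
    tr <- sort(sample.int(n, half))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
  parts <- lapply(splits, function(sp) {
    str <- sys_builder(sp$train)
    ste <- sys_builder(sp$test)
    atr <- moment_design(str, phi)
    ate <- moment_design(ste, phi)
    list(ata = crossprod(atr), atb = crossprod(atr, str$b),
         ate = ate, bte = ste$b)
  })
  score <- function(log10_lambda) {
    lam <- 10^log10_lambda
    mean(vapply(parts, function(pt) {
      g <- solve_or_pinv(pt$ata + lam * s, pt$atb)
      sum((pt$ate %*% g - pt$bte)^2)
    }, numeric(1)))
  }
  opt <- stats::optimize(score, interval = c(-8, 8), tol = 1e-3)
  10^opt$minimum
}

#' Solve the shape-constrained additive co-data model
#'
#' Minimises the penalised moment criterion of the additive model subject
#' to linear shape constraints on the spline coefficients (a convex
#' quadratic program, solved by `pracma::lsqlincon`): positivity,
#' monotonicity and/or convexity in `M gamma <= b` form plus optional
#' equality constraints.
#'
#' @param sys A `moment_system`.
#' @param phi p-by-J spline expansion.
#' @param s J-by-J difference penalty.
#' @param lambda Smoothing penalty (scalar, >= 0).
#' @param constraints List with `m_ineq`, `b_ineq` and optionally `m_eq`,
#'   `b_eq` (see [shape_constraints()]).
#' @return List: `gamma`, `v`, `a`, `kkt` (stationarity residual).
#' @export
solve_scam_codata <- function(sys, phi, s, lambda, constraints) {
  phi <- as.matrix(phi)
  a <- moment_design(sys, phi)
  rt <- mat_sqrt_psd(lambda * s)
  c_aug <- rbind(a, rt)
  d_aug <- c(sys$b, numeric(nrow(rt)))
  meq <- constraints$m_eq
  beq <- constraints$b_eq
  if (is.null(meq) || nrow(meq) == 0L) { meq <- NULL; beq <- NULL }
  gamma <- tryCatch(
    pracma::lsqlincon(c_aug, d_aug,
                      A = constraints$m_ineq, b = constraints$b_ineq,
                      Aeq = meq, beq = beq),
    error = function(e) {
      if (grepl("inconsisten|infeasib", conditionMessage(e),
                ignore.case = TRUE))
        stop("infeasible shape-constraint system", call. = FALSE)
      # jitter the Hessian once for near-singular quadratics
      c2 <- rbind(c_aug, sqrt(1e-8 * mean(colSums(c_aug^2))) * diag(ncol(a)))
      pracma::lsqlincon(c2, c(d_aug, numeric(ncol(a))),
                        A = constraints$m_ineq, b = constraints$b_ineq,
                        Aeq = meq, beq = beq)
    })
  gamma <- drop(gamma)
  viol <- max(c(constraints$m_ineq %*% gamma - constraints$b_ineq, 0))
  if (viol > 1e-8)
    warning("constraint violation ", format(viol), " above tolerance",
            call. = FALSE)
  kkt <- scam_kkt_residual(a, sys$b, lambda * s, gamma, constraints)
  list(gamma = gamma, v = pmax(drop(phi %*% gamma), 0), a = a, kkt = kkt)
}

# stationarity residual: || grad + M_act' mu ||_inf with mu >= 0 fitted by
# NNLS over the active constraint rows
scam_kkt_residual <- function(a, b, pen, gamma, constraints, act_tol = 1e-7) {
  grad <- 2 * drop(crossprod(a, a %*% gamma - b)) + 2 * drop(pen %*% gamma)
  m <- constraints$m_ineq
  act <- which(abs(m %*% gamma - constraints$b_ineq) < act_tol)
  if (length(act) == 0L) return(max(abs(grad)))
  mt <- t(m[act, , drop = FALSE])
  mu <- tryCatch(pracma::lsqnonneg(mt, -grad)$x,
                 error = function(e) rep(0, length(act)))
  max(abs(grad + mt %*% mu))
}

#' Non-negative co-data source weights
#'
#' Blends per-source prior-variance contributions by non-negative least
#' squares on the moment system: \eqn{\hat w = argmin_{w\ge 0}
#' \|\sum_d w_d (C\circ C)\,contrib_d - b\|_2^2}.
#'
#' @param contributions List of length-p vectors \eqn{Z^{(d)}\gamma^{(d)}}.
#' @param sys A `moment_system`.
#' @return Length-D non-negative weight vector.
#' @export
estimate_source_weights <- function(contributions, sys) {
  stopifnot(length(contributions) >= 1L)
  bmat <- moment_design(sys, do.call(cbind, contributions))
  if (all(bmat == 0)) {
    warning("all source contributions are zero; returning zero weights",
            call. = FALSE)
    return(rep(0, length(contributions)))
  }
  if (ncol(bmat) == 1L)
    return(max(sum(bmat * sys$b) / sum(bmat^2), 0))
  drop(pracma::lsqnonneg(bmat, sys$b)$x)
}
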