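# Main fitting routine: co-data adaptive ridge regression.
#
# Stage order follows the sequential empirical Bayes scheme: initial
# constant ridge penalty by cross-validation; initial fit and IRLS weights;
# global scale from the one-group moment system; per-source co-data
# coefficients (linear / penalised / constrained solve, smoothing penalty
# by random splits where needed); non-negative source weights; assembly of
# prior variances with a final scalar rescale against the intercept moment
# equation; final weighted ridge fit.

#' Cross-validated constant ridge penalty
#'
#' Selects a single ridge penalty by K-fold cross-validated deviance over
#' a log-spaced grid, using per-fold Gram matrices so the grid sweep costs
#' O(n^3) per fold rather than a full refit.
#'
#' @param data A [codapen_data()] object.
#' @param grid Candidate penalties; a log-spaced default spanning
#'   `1e-2 * p` to `1e4 * p` when `NULL`.
#' @param nfolds Number of folds (default 10).
#' @param intercept Include an unpenalised intercept (non-cox).
#' @return List: `lambda` (selected penalty), `cv` (deviance per grid
#'   point), `grid`.
#' @export
cv_constant_ridge <- function(data, grid = NULL, nfolds = 10L,
                              intercept = TRUE) {
  n <- data$n
  fam <- data$family$name
  if (is.null(grid))
    grid <- exp(seq(log(1e-2 * data$p), log(1e4 * data$p), length.out = 21))
  nfolds <- min(nfolds, n)
  folds <- sample(rep_len(seq_len(nfolds), n))
  use_int <- intercept && fam != "cox"
  dev <- matrix(NA_real_, nfolds, length(grid))
  for (f in seq_len(nfolds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (fam == "cox") {
      dtr <- codapen_data(data$x[tr, , drop = FALSE],
                          data$y[tr, , drop = FALSE], data$family)
      for (j in seq_along(grid)) {
        fit <- suppressWarnings(fit_weighted_ridge(dtr, grid[j],
                                                   intercept = FALSE))
        eta_te <- drop(data$x[te, , drop = FALSE] %*% fit$beta)
        pl <- cox_parts(data$y[te, 1L], data$y[te, 2L], eta_te)$ll
        dev[f, j] <- -2 * pl
      }
    } else {
      dev[f, ] <- cv_fold_glm(data$x, data$y, tr, te, grid, fam, use_int)
    }
  }
  cv <- colMeans(dev)
  list(lambda = grid[which.min(cv)], cv = cv, grid = grid)
}

# dual-form grid sweep for one fold: the train Gram X_tr X_tr' is built
# once; each (lambda, IRLS iteration) is an n_tr x n_tr solve
cv_fold_glm <- function(x, y, tr, te, grid, fam, use_int) {
  xtr <- x[tr, , drop = FALSE]
  xte <- x[te, , drop = FALSE]
  ytr <- y[tr]
  if (use_int) {
    xm <- colMeans(xtr)
    xtr <- sweep(xtr, 2L, xm)
    xte <- sweep(xte, 2L, xm)
  }
  gtr <- tcrossprod(xtr)
  cross <- tcrossprod(xte, xtr)
  ntr <- length(tr)
  out <- numeric(length(grid))
  for (j in seq_along(grid)) {
    lam <- grid[j]
    if (fam == "gaussian") {
      ym <- if (use_int) mean(ytr) else 0
      alpha <- solve(gtr / lam + diag(ntr), ytr - ym)
      eta_te <- drop(cross %*% alpha) / lam + ym
      out[j] <- mean((y[te] - eta_te)^2)
    } else {
      eta <- rep(0, ntr)
      b0 <- 0
      for (it in 1:50) {
        mu <- 1 / (1 + exp(-eta - b0))
        w <- pmax(mu * (1 - mu), 1e-10)
        z <- eta + b0 + (ytr - mu) / w
        if (use_int) {
          zm <- sum(z * w) / sum(w)
        } else zm <- 0
        kk <- gtr / lam
        diag(kk) <- diag(kk) + 1 / w
        alpha <- solve(kk, z - zm)
        eta_new <- drop(gtr %*% alpha) / lam
        b0_new <- zm
        if (max(abs(eta_new + b0_new - eta - b0)) < 1e-6) {
          eta <- eta_new; b0 <- b0_new; break
        }
        eta <- eta_new; b0 <- b0_new
      }
      eta_te <- drop(cross %*% alpha) / lam + b0
      mu_te <- pmin(pmax(1 / (1 + exp(-eta_te)), 1e-10), 1 - 1e-10)
      out[j] <- -2 * mean(y[te] * log(mu_te) + (1 - y[te]) * log(1 - mu_te))
    }
  }
  out
}

#' Co-data adaptive ridge regression
#'
#' Fits a generalised linear or Cox model with variable-specific ridge
#' penalties adapted to one or more co-data sources.  Per-variable normal
#' prior variances are regressed on the co-data through the source's
#' co-data model (linear, generalised additive, or shape-constrained
#' additive) and estimated by empirical Bayes moment estimation; the final
#' model is refitted with penalties inversely proportional to the fitted
#' prior variances.
#'
#' @param x n-by-p observation matrix.
#' @param y Response (see [codapen_data()]).
#' @param codata A [codata_source()], a list of them, or a plain p-by-G
#'   matrix (treated as a linear co-data source).
#' @param family `"gaussian"`, `"binomial"` or `"cox"`.
#' @param intercept Include an unpenalised intercept (non-cox).
#' @param lambda_init Initial constant ridge penalty; cross-validated when
#'   `NULL`.
#' @param block_size Block size for the moment-system computation.
#' @param n_splits Random splits for smoothing-penalty estimation.
#' @param seed Integer seed governing the cross-validation folds and the
#'   random splits.
#' @param floor_eps Prior-variance floor: variances below
#'   `floor_eps * median(positive variances)` are raised to that floor so
#'   the final penalties stay finite.
#' @param fixed Optional list pinning prior parameters instead of
#'   estimating them: `tau2`, `w`, `gamma` (list, one vector per source).
#' @return A `codapen` object: `fit` (final `codapen_ridge`), `prior`
#'   (`tau2_global`, `tau2_marginal`, `w`, `v`, per-source `gamma`,
#'   `lambda`), `initial` (`lambda_init`, `omega_tilde`, diagnostics) and
#'   `report` (structured stage log).
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(60 * 40), 60, 40)
#' z <- runif(40)
#' beta <- rnorm(40, 0, sqrt(0.01 + 0.2 * z))
#' y <- drop(x %*% beta) + rnorm(60)
#' fit <- codapen(x, y, z, family = "gaussian", seed = 1)
#' @export
codapen <- function(x, y, codata, family = "gaussian", intercept = TRUE,
                    lambda_init = NULL, block_size = 500L, n_splits = 10L,
                    seed = 1L, floor_eps = 1e-6, fixed = list()) {
  data <- codapen_data(x, y, family)
  sources <- normalise_sources(codata, data$p)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  use_int <- intercept && data$family$name != "cox"
  report <- list(seed = as.integer(seed), family = data$family$name,
                 n = data$n, p = data$p, n_sources = length(sources))

  # (1) initial constant ridge level
  stage <- "initial_ridge_cv"
  res <- with_stage(stage, {
    if (is.null(lambda_init))
      cv_constant_ridge(data, nfolds = 10L, intercept = use_int)$lambda
    else lambda_init
  })
  lambda0 <- res
  report$lambda_init <- lambda0

  # (2) initial fit and IRLS weights
  fit0 <- with_stage("initial_fit",
    fit_weighted_ridge(data, lambda0, intercept = use_int))
  w <- with_stage("irls_weights", irls_weights(fit0, data))
  omega_tilde <- if (data$family$name == "gaussian")
    lambda0 / fit0$sigma2 else lambda0
  cdat <- if (use_int) center_data(data, w) else data
  sys <- with_stage("moment_system",
    build_moment_system(cdat, w, omega_tilde, fit0$beta,
                        block_size = block_size))
  report$omega_tilde <- omega_tilde
  report$initial_converged <- fit0$converged

  # (3) global scale from the one-group system
  tau2_marg <- with_stage("global_tau",
    solve_scalar_ls(drop(moment_design(sys, rep(1, data$p))), sys$b))
  report$tau2_marginal <- tau2_marg

  # (4) per-source co-data coefficients
  fits <- with_stage("codata_models", lapply(seq_along(sources), function(d) {
    src <- sources[[d]]
    if (!is.null(fixed$gamma)) {
      gam <- fixed$gamma[[d]]
      zmat <- if (src$model == "linear") src$z else src$phi
      return(list(gamma = gam, v = pmax(drop(zmat %*% gam), 0),
                  lambda = src$lambda, contribution = drop(zmat %*% gam)))
    }
    sf <- fit_codata_source(src, sys, cdat, data, lambda0, use_int,
                            n_splits, seed, block_size)
    sf
  }))
  contributions <- lapply(fits, `[[`, "contribution")

  # (5) non-negative source weights
  wsrc <- with_stage("source_weights", {
    if (!is.null(fixed$w)) rep_len(fixed$w, length(sources))
    else if (length(sources) == 1L) 1
    else estimate_source_weights(contributions, sys)
  })

  # (6) assemble prior variances; final scalar rescale against the moment
  # system keeps the overall level consistent after truncation/blending
  v_raw <- Reduce(`+`, Map(`*`, contributions, as.list(wsrc)))
  v_pos <- pmax(v_raw, 0)
  if (!is.null(fixed$tau2)) {
    tau2 <- fixed$tau2
  } else if (max(v_pos) <= 0) {
    tau2 <- 0
  } else {
    tau2 <- solve_scalar_ls(drop(moment_design(sys, v_pos)), sys$b)
  }
  v <- tau2 * v_pos
  agnostic <- max(v) <= 0
  if (agnostic && is.null(fixed$tau2)) {
    # no co-data signal: fall back to a constant prior, i.e. the
    # cross-validated constant-ridge model
    v <- rep(if (data$family$name == "gaussian")
      fit0$sigma2 / lambda0 else 1 / lambda0, data$p)
    report$codata_agnostic_fallback <- TRUE
  }
  report$tau2_global <- tau2
  report$w <- wsrc

  # (7) penalties with a variance floor, final adaptive fit.  The global
  # penalty level is anchored to the cross-validated constant ridge: the
  # floored prior variances are normalised to mean one and scaled by
  # 1/lambda0, so constant co-data reproduces the constant-ridge fit
  # exactly while relative penalisation follows the co-data model.
  med <- stats::median(v[v > 0])
  floor_v <- floor_eps * med
  n_floored <- sum(v < floor_v)
  v_fl <- pmax(v, floor_v)
  penalties <- lambda0 * mean(v_fl) / v_fl
  fit <- with_stage("final_fit",
    fit_weighted_ridge(data, penalties, intercept = use_int))
  report$n_floored <- n_floored
  report$final_converged <- fit$converged
  report$v_quantiles <- stats::quantile(v_fl, c(0, .25, .5, .75, 1))

  structure(list(
    fit = fit,
    prior = list(tau2_global = tau2, tau2_marginal = tau2_marg, w = wsrc,
                 v = v_fl, v_untruncated = v_raw,
                 sources = lapply(fits, function(f)
                   f[c("gamma", "lambda")])),
    sources = sources,
    initial = list(lambda_init = lambda0, omega_tilde = omega_tilde,
                   fit = fit0),
    penalties = penalties,
    report = report
  ), class = "codapen")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

normalise_sources <- function(codata, p) {
  if (inherits(codata, "codata_source")) codata <- list(codata)
  if (!is.list(codata)) codata <- list(codata_source(as.matrix(codata)))
  codata <- lapply(codata, function(s)
    if (inherits(s, "codata_source")) s else codata_source(as.matrix(s)))
  for (s in codata)
    if (nrow(s$z) != p) stop("co-data must have one row per variable")
  codata
}

# per-source estimation dispatch; returns gamma, v, lambda, contribution
fit_codata_source <- function(src, sys, cdat, data, lambda0, use_int,
                              n_splits, seed, block_size) {
  if (src$model == "linear") {
    sol <- solve_linear_codata(sys, src$z)
    return(list(gamma = sol$gamma, v = sol$v, lambda = NULL,
                contribution = drop(src$z %*% sol$gamma)))
  }
  # smoothing penalties: fixed if supplied, else random splits per co-data
  # variable on the subset moment systems
  blocks <- src$blocks
  G <- length(blocks)
  lambdas <- src$lambda
  if (is.null(lambdas)) {
    builder <- subset_system_builder(data, lambda0, use_int, block_size)
    lambdas <- vapply(seq_len(G), function(g)
      estimate_smoothing_penalty(builder, data$n,
                                 src$phi[, blocks[[g]], drop = FALSE],
                                 src$s_list[[g]], n_splits = n_splits,
                                 seed = seed + g), numeric(1))
  } else lambdas <- rep_len(lambdas, G)
  if (src$model == "gam") {
    sol <- solve_gam_codata(sys, src$phi, src$s_list, lambdas, blocks)
  } else {
    con <- stack_constraints(src$constraints, blocks, ncol(src$phi))
    s_all <- matrix(0, ncol(src$phi), ncol(src$phi))
    for (g in seq_len(G))
      s_all[blocks[[g]], blocks[[g]]] <- lambdas[g] * src$s_list[[g]]
    sol <- solve_scam_codata(sys, src$phi, s_all, 1, con)
  }
  list(gamma = sol$gamma, v = sol$v, lambda = lambdas,
       contribution = drop(src$phi %*% sol$gamma))
}

# closure refitting the initial ridge on a sample subset and building its
# moment system, as required by the random-splits penalty estimator
subset_system_builder <- function(data, lambda0, use_int, block_size) {
  function(idx) {
    sub <- codapen_data(data$x[idx, , drop = FALSE],
                        if (data$family$name == "cox")
                          data$y[idx, , drop = FALSE] else data$y[idx],
                        data$family)
    initial_moment_system(sub, lambda0, intercept = use_int,
                          block_size = block_size)
  }
}

stack_constraints <- function(con_list, blocks, ncol_total) {
  m <- NULL; b <- numeric(0)
  for (g in seq_along(con_list)) {
    mg <- con_list[[g]]$m_ineq
    wide <- matrix(0, nrow(mg), ncol_total)
    wide[, blocks[[g]]] <- mg
    m <- rbind(m, wide)
    b <- c(b, con_list[[g]]$b_ineq)
  }
  list(m_ineq = m, b_ineq = b,
       m_eq = matrix(0, 0L, ncol_total), b_eq = numeric(0))
}

#' Fitted prior-variance curve of a co-data source
#'
#' Evaluates the source's fitted contribution to the prior variance on a
#' grid of co-data values (single continuous co-data variable sources).
#'
#' @param object A `codapen` fit.
#' @param source Source index.
#' @param grid Co-data values at which to evaluate; defaults to an
#'   equispaced grid over the observed range.
#' @return Data frame with columns `z` and `v`.
#' @export
prior_variance_curve <- function(object, source = 1L, grid = NULL) {
  src <- object$sources[[source]]
  gamma <- object$prior$sources[[source]]$gamma
  scale <- object$prior$tau2_global * object$prior$w[source]
  if (src$model == "linear") {
    if (ncol(src$z) != 1L)
      stop("curve evaluation needs a single co-data variable")
    if (is.null(grid))
      grid <- seq(min(src$z), max(src$z), length.out = 100L)
    v <- pmax(grid * gamma, 0) * scale
  } else {
    if (length(src$blocks) != 1L)
      stop("curve evaluation needs a single co-data variable")
    phi <- src$phi_bases[[1L]]
    if (is.null(grid)) {
      r <- attr(phi, "range")
      grid <- seq(r[1], r[2], length.out = 100L)
    }
    v <- pmax(drop(eval_spline_basis(phi, grid) %*% gamma), 0) * scale
  }
  data.frame(z = grid, v = v)
}

#' @export
predict.codapen <- function(object, xnew, ...) {
  predict_response(object$fit, xnew)
}

#' @export
print.codapen <- function(x, ...) {
  cat("<codapen> co-data adaptive", x$fit$family$name, "ridge fit\n")
  cat("  n =", x$fit$n, ", p =", x$fit$p, ",", length(x$sources),
      "co-data source(s)\n")
  cat("  tau2_global =", format(x$prior$tau2_global, digits = 4),
      "; source weights:", format(x$prior$w, digits = 3), "\n")
  invisible(x)
}

#' Write a structured fit report as JSON
#'
#' Serialises the stage-level estimates of a `codapen` fit (global scale,
#' source weights, co-data coefficients, smoothing penalties, prior
#' variance quantiles, convergence flags) to a JSON file.
#'
#' @param object A `codapen` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(object, path) {
  rep <- object$report
  out <- list(
    family = rep$family, n = rep$n, p = rep$p, seed = rep$seed,
    lambda_init = rep$lambda_init, omega_tilde = rep$omega_tilde,
    tau2_global = rep$tau2_global, tau2_marginal = rep$tau2_marginal,
    w = as.numeric(rep$w),
    sources = lapply(object$prior$sources, function(s)
      list(gamma = as.numeric(s$gamma),
           lambda = if (is.null(s$lambda)) NULL else as.numeric(s$lambda))),
    v_quantiles = as.list(stats::setNames(as.numeric(rep$v_quantiles),
                                          names(rep$v_quantiles))),
    n_floored = rep$n_floored,
    initial_converged = rep$initial_converged,
    final_converged = rep$final_converged
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
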