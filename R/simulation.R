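# Synthetic-data generator and benchmark harness.
#
# The generator emulates the simulation designs used to benchmark co-data
# models: a continuous co-data variable Z_k ~ U(0,1) per variable, true
# prior variances v0(Z_k) following a stated relation (constant / linear /
# convex / monotone step), true coefficients beta0_k ~ N(0, v0(Z_k)),
# gaussian X, and gaussian or binomial response.  "Random" co-data is the
# informative co-data permuted after drawing beta0, severing the relation
# while keeping both marginals.

#' Declare a simulation design
#'
#' @param n,p Training sample and variable counts (test sets match `n`).
#' @param family `"gaussian"` or `"binomial"`.
#' @param codata_kind `"informative"` or `"random"` (co-data permuted
#'   after the coefficients are drawn).
#' @param relation Shape of the true prior-variance-vs-co-data relation:
#'   `constant` (`c`), `linear` (`a + b z`), `convex` (`a + b z^2`),
#'   `monotone_step` (`lo` below `threshold`, `hi` above).
#' @param params Named list overriding the relation parameters; defaults:
#'   constant `c = 0.1`; linear `a = 0.01, b = 0.1`; convex
#'   `a = 0.01, b = 0.2`; monotone_step `lo = 0.01, hi = 0.1,
#'   threshold = 0.5`.
#' @param noise_sd Gaussian response noise standard deviation.
#' @param sparse_frac Fraction of coefficients set exactly to zero (sparse
#'   selection designs).  For informative co-data the non-zero probability
#'   increases with the co-data value (the co-data informs both effect
#'   location and size); its mean equals `1 - sparse_frac`.
#' @param n_replicates Default replicate count for the harnesses.
#' @param seed Base seed; replicate `r` uses a seed derived from
#'   `(seed, r)` so replicates are reproducible in any execution order.
#' @export
sim_design <- function(n = 150L, p = 1000L, family = "gaussian",
                       codata_kind = c("informative", "random"),
                       relation = c("linear", "constant", "convex",
                                    "monotone_step"),
                       params = list(), noise_sd = 1, sparse_frac = 0,
                       n_replicates = 20L, seed = 1L) {
  relation <- match.arg(relation)
  codata_kind <- match.arg(codata_kind)
  defaults <- switch(relation,
    constant      = list(c = 0.1),
    linear        = list(a = 0.01, b = 0.1),
    convex        = list(a = 0.01, b = 0.2),
    monotone_step = list(lo = 0.01, hi = 0.1, threshold = 0.5))
  params <- utils::modifyList(defaults, params)
  if (any(unlist(params) < 0))
    stop("variance parameters must be non-negative")
  if (sparse_frac < 0 || sparse_frac >= 1)
    stop("sparse_frac must lie in [0, 1)")
  structure(list(n = as.integer(n), p = as.integer(p), family = family,
                 codata_kind = codata_kind, relation = relation,
                 params = params, noise_sd = noise_sd,
                 sparse_frac = sparse_frac,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' True prior variance as a function of the co-data
#'
#' @param design A [sim_design()].
#' @param z Co-data values in `[0, 1]`.
#' @export
true_variance <- function(design, z) {
  pr <- design$params
  switch(design$relation,
    constant      = rep(pr$c, length(z)),
    linear        = pr$a + pr$b * z,
    convex        = pr$a + pr$b * z^2,
    monotone_step = ifelse(z < pr$threshold, pr$lo, pr$hi))
}

replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(replicate) * 7919) %%
               2147483629)
}

#' Draw one synthetic train/test replicate
#'
#' @param design A [sim_design()].
#' @param replicate Replicate index (determines the seed together with
#'   the design seed).
#' @return List: `train`, `test` ([codapen_data()] of equal size), `z`
#'   (length-p co-data), `beta0`, `v0` (true prior variances at `z`).
#' @export
simulate_dataset <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "sim_design"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(replicate_seed(design$seed, replicate))
  n <- design$n; p <- design$p
  z <- stats::runif(p)
  v0 <- true_variance(design, z)
  if (any(v0 < 0)) stop("negative true prior variance")
  beta0 <- stats::rnorm(p, 0, sqrt(v0))
  if (design$sparse_frac > 0) {
    q <- 1 - design$sparse_frac
    pnz <- pmin(2 * q * z, 1)          # mean over U(0,1) co-data is q
    beta0 <- beta0 * stats::rbinom(p, 1L, pnz)
  }
  if (design$codata_kind == "random") z <- sample(z)
  draw <- function() {
    x <- matrix(stats::rnorm(n * p), n, p)
    eta <- drop(x %*% beta0)
    y <- switch(design$family,
      gaussian = eta + stats::rnorm(n, 0, design$noise_sd),
      binomial = stats::rbinom(n, 1L, 1 / (1 + exp(-eta))))
    codapen_data(x, y, design$family)
  }
  list(train = draw(), test = draw(), z = z, beta0 = beta0, v0 = v0)
}

test_metric <- function(fit, test) {
  if (test$family$name == "gaussian") {
    mean((test$y - predict_response(fit, test$x))^2)
  } else {
    auc(predict_response(fit, test$x), test$y)
  }
}

# rank-based (Wilcoxon) area under the ROC curve
auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

codata_model_source <- function(model, z, n_basis = 20L) {
  switch(model,
    linear   = codata_source(cbind(intercept = 1, z = z), "linear"),
    gam      = codata_source(z, "gam", n_basis = n_basis),
    scam_p   = codata_source(z, "scam", n_basis = n_basis,
                             shapes = "positive"),
    scam_pmi = codata_source(z, "scam", n_basis = n_basis,
                             shapes = c("positive", "monotone_increasing")),
    stop("unknown co-data model: ", model))
}

#' Compare co-data models on synthetic replicates
#'
#' Fits each requested co-data model (and/or the co-data agnostic
#' cross-validated ridge) on replicate training sets and evaluates test
#' error and the fitted prior-variance curve on a co-data grid.
#'
#' @param design A [sim_design()].
#' @param models Subset of `linear`, `gam`, `scam_p`, `scam_pmi`,
#'   `agnostic_ridge`.
#' @param n_replicates Number of replicates (default from the design).
#' @param grid_size Co-data grid points for the fitted curves.
#' @param n_basis Spline basis size for the additive models.
#' @param n_splits Random splits for smoothing-penalty estimation.
#' @return List of two data frames: `metrics` (replicate, model, metric —
#'   test MSE for gaussian, AUC for binomial — and wall time, with failed
#'   replicates marked) and `curves` (replicate, model, z, fitted v).
#' @export
run_codata_model_comparison <- function(design,
                                        models = c("linear", "gam",
                                                   "agnostic_ridge"),
                                        n_replicates = design$n_replicates,
                                        grid_size = 50L, n_basis = 20L,
                                        n_splits = 10L) {
  grid <- seq(0, 1, length.out = grid_size)
  metrics <- list(); curves <- list()
  for (r in seq_len(n_replicates)) {
    sim <- simulate_dataset(design, r)
    for (m in models) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        if (m == "agnostic_ridge") {
          set.seed(replicate_seed(design$seed, r) + 1L)
          lam <- cv_constant_ridge(sim$train)$lambda
          fit <- fit_weighted_ridge(sim$train, lam)
          list(metric = test_metric(fit, sim$test), v = rep(NA_real_,
                                                            grid_size))
        } else {
          src <- codata_model_source(m, sim$z, n_basis)
          cfit <- codapen(sim$train$x, sim$train$y, src,
                          family = design$family,
                          seed = replicate_seed(design$seed, r) + 1L,
                          n_splits = n_splits)
          vhat <- if (m == "linear")
            pmax(cbind(1, grid) %*% cfit$prior$sources[[1]]$gamma, 0) *
              cfit$prior$tau2_global
          else prior_variance_curve(cfit, grid = grid)$v
          list(metric = test_metric(cfit$fit, sim$test), v = drop(vhat))
        }
      }, error = function(e) {
        warning("replicate ", r, " model ", m, " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      el <- proc.time()[["elapsed"]] - t0
      if (is.null(res)) {
        metrics[[length(metrics) + 1L]] <-
          data.frame(replicate = r, model = m, metric = NA_real_,
                     time = el, failed = TRUE)
      } else {
        metrics[[length(metrics) + 1L]] <-
          data.frame(replicate = r, model = m, metric = res$metric,
                     time = el, failed = FALSE)
        curves[[length(curves) + 1L]] <-
          data.frame(replicate = r, model = m, z = grid, v = res$v)
      }
    }
  }
  list(metrics = do.call(rbind, metrics),
       curves = do.call(rbind, curves))
}

#' Summarise comparison curves into pointwise quantile bands
#'
#' @param curves `curves` data frame from
#'   [run_codata_model_comparison()].
#' @return Data frame with pointwise median and 25--75% / 5--95% bands
#'   per model and grid point.
#' @export
summarise_curves <- function(curves) {
  out <- list()
  for (m in unique(curves$model)) {
    cm <- curves[curves$model == m & !is.na(curves$v), ]
    if (nrow(cm) == 0L) next
    for (zv in unique(cm$z)) {
      v <- cm$v[cm$z == zv]
      q <- stats::quantile(v, c(.05, .25, .5, .75, .95))
      out[[length(out) + 1L]] <- data.frame(
        model = m, z = zv, median = q[[3]], q25 = q[[2]], q75 = q[[4]],
        q05 = q[[1]], q95 = q[[5]])
    }
  }
  do.call(rbind, out)
}

sens_prec <- function(selected, truth_nonzero) {
  npos <- length(truth_nonzero)
  tp <- length(intersect(selected, truth_nonzero))
  list(sensitivity = if (npos == 0) NA_real_ else tp / npos,
       precision = if (length(selected) == 0) NA_real_
                   else tp / length(selected))
}

# bisection on a global penalty multiplier so the uniform elastic net
# selects (approximately) a target number of variables
match_selection_size <- function(data, lambda_base, alpha, target,
                                 max_iter = 30L) {
  lo <- 1e-4; hi <- 1e4
  fit <- NULL
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    fit <- suppressWarnings(
      fit_adaptive_elastic_net(data, rep(lambda_base * mid, data$p), alpha))
    k <- sum(fit$beta != 0)
    if (k == target || (hi / lo) < 1.01) break
    if (k > target) lo <- mid else hi <- mid
  }
  fit
}

#' Compare co-data-adaptive and uniform elastic-net selection
#'
#' On sparse synthetic truths, fits the co-data adaptive pipeline
#' (adaptive ridge, penalties transformed to elastic net) and a uniform
#' elastic net whose global penalty is tuned to select the same number of
#' variables, and reports sensitivity, precision and test error per
#' replicate.
#'
#' @param design A [sim_design()] with `sparse_frac > 0`.
#' @param alpha Elastic-net mixing used by both methods.
#' @param n_replicates Number of replicates.
#' @param codata_model Co-data model for the adaptive method (default
#'   `"gam"`).
#' @param n_basis,n_splits Spline settings passed through.
#' @return Data frame: replicate, method, sensitivity, precision
#'   (`NA` when nothing is selected), selected count, test MSE.
#' @export
run_selection_comparison <- function(design, alpha = 0.5,
                                     n_replicates = design$n_replicates,
                                     codata_model = "gam",
                                     n_basis = 20L, n_splits = 10L) {
  if (design$sparse_frac <= 0)
    stop("selection comparison needs a sparse truth (sparse_frac > 0)")
  out <- list()
  for (r in seq_len(n_replicates)) {
    sim <- simulate_dataset(design, r)
    truth <- which(sim$beta0 != 0)
    src <- codata_model_source(codata_model, sim$z, n_basis)
    cfit <- codapen(sim$train$x, sim$train$y, src, family = design$family,
                    seed = replicate_seed(design$seed, r) + 1L,
                    n_splits = n_splits)
    ad <- suppressWarnings(sparsify_fit(cfit, sim$train, alpha))
    ad_sel <- select_variables(ad)
    un <- match_selection_size(sim$train, mean(ad$lambda_k), alpha,
                               target = ad_sel$count)
    for (method in c("adaptive_en", "uniform_en")) {
      fit <- if (method == "adaptive_en") ad else un
      sp <- sens_prec(which(fit$beta != 0), truth)
      out[[length(out) + 1L]] <- data.frame(
        replicate = r, method = method,
        sensitivity = sp$sensitivity, precision = sp$precision,
        selected = sum(fit$beta != 0),
        metric = test_metric(fit, sim$test))
    }
  }
  do.call(rbind, out)
}
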