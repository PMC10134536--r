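# File input/output and configuration-driven workflows.
#
# Conventions: dense matrices travel as CSV/TSV with a header row naming
# variables; sparse matrices as Matrix Market; group sets as JSON mapping
# group name -> 1-based variable indices; run configurations as YAML.

#' Load an observation matrix and response from files
#'
#' @param x_path Path to the observation matrix: CSV/TSV with a header
#'   row (rows = samples, columns = variables) or Matrix Market (`mtx`).
#' @param y_path Path to the response: CSV/TSV with one column (gaussian /
#'   binomial) or two columns `time,event` (cox).
#' @param family Response family name.
#' @param format `"csv"`, `"tsv"` or `"mtx"` for `x_path`; the response is
#'   always delimited text.
#' @return A [codapen_data()] with variable names preserved.
#' @export
load_dataset <- function(x_path, y_path, family = "gaussian",
                         format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  for (f in c(x_path, y_path))
    if (!file.exists(f)) stop("file not found: ", f)
  x <- switch(format,
    csv = as.matrix(utils::read.csv(x_path, check.names = FALSE)),
    tsv = as.matrix(utils::read.delim(x_path, check.names = FALSE)),
    mtx = as.matrix(Matrix::readMM(x_path)))
  if (!is.numeric(x)) stop("non-numeric entries in ", x_path)
  ytab <- utils::read.csv(y_path, check.names = FALSE,
                          sep = if (grepl("\\.tsv$", y_path)) "\t" else ",")
  fam <- response_family(family)
  y <- if (fam$name == "cox") as.matrix(ytab[, 1:2]) else ytab[[1L]]
  ny <- if (is.matrix(y)) nrow(y) else length(y)
  if (ny != nrow(x))
    stop(sprintf("response has %d rows but x has %d", ny, nrow(x)))
  d <- codapen_data(x, y, fam)
  d$names <- colnames(x)
  d
}

#' Write a matrix in Matrix Market format
#' @param x Matrix.
#' @param path Output `.mtx` path.
#' @export
write_mtx <- function(x, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x), "CsparseMatrix"),
                              "generalMatrix"), path)
  invisible(path)
}

#' Read a group set from JSON
#'
#' JSON object mapping group names to arrays of 1-based variable indices.
#'
#' @param path JSON file path.
#' @return Named list of integer vectors.
#' @export
read_groups <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(g, as.integer)
}

config_schema <- list(
  x = "character", y = "character", format = "character",
  family = "character", codata = "list", alpha = "numeric",
  block_size = "numeric", n_splits = "numeric", seed = "numeric",
  outdir = "character")

codata_schema <- list(
  path = "character", groups = "character", model = "character",
  n_basis = "numeric", degree = "numeric", diff_order = "numeric",
  shapes = "character", lambda = "numeric", missing = "character")

#' Validate and normalise a run configuration
#'
#' @param config Named list (e.g. from a YAML file); unknown keys are
#'   rejected before any computation.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (req in c("x", "y", "family", "codata", "outdir"))
    if (is.null(config[[req]])) stop("missing configuration key: ", req)
  for (src in config$codata) {
    bad <- setdiff(names(src), names(codata_schema))
    if (length(bad) > 0)
      stop("unknown co-data keys: ", paste(bad, collapse = ", "))
    if (is.null(src$path) && is.null(src$groups))
      stop("each co-data source needs 'path' or 'groups'")
  }
  config$format <- config$format %||% "csv"
  config$seed <- as.integer(config$seed %||% 1L)
  config$block_size <- as.integer(config$block_size %||% 500L)
  config$n_splits <- as.integer(config$n_splits %||% 10L)
  config
}

load_codata_source <- function(src, p) {
  if (!is.null(src$groups)) {
    z <- z_from_groupset(read_groups(src$groups), p)
    return(codata_source(z, model = "linear", name = src$groups))
  }
  z <- as.matrix(utils::read.csv(src$path, check.names = FALSE,
                                 sep = if (grepl("\\.tsv$", src$path))
                                   "\t" else ","))
  if (anyNA(z))
    z <- handle_missing_codata(z, informative =
                                 identical(src$missing, "informative"))
  codata_source(z, model = src$model %||% "linear",
                n_basis = as.integer(src$n_basis %||% 20L),
                degree = as.integer(src$degree %||% 3L),
                diff_order = as.integer(src$diff_order %||% 2L),
                shapes = src$shapes %||% "positive",
                lambda = src$lambda, name = src$path)
}

#' Run a fit workflow from a configuration
#'
#' Loads the data and co-data named in the configuration, runs the
#' co-data adaptive fit (and, when `alpha` is set, the elastic-net
#' transform and sparse fit), and writes the fit report (JSON), the
#' coefficient table (TSV), a selected-variable table (TSV, sparse runs)
#' and a stage log to the output directory.  On failure, partial
#' artefacts are removed.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, the list of artefact paths.
#' @export
run_fit_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  arts <- file.path(config$outdir,
                    c("fit_report.json", "coefficients.tsv",
                      "selection.tsv", "log.txt"))
  names(arts) <- c("report", "coefficients", "selection", "log")
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%OS2"), ...,
                            "\n", file = arts[["log"]], append = TRUE)
  cat("", file = arts[["log"]])
  written <- arts[["log"]]
  logf("seed:", config$seed)
  data <- load_dataset(config$x, config$y, config$family, config$format)
  logf("loaded n =", data$n, "p =", data$p)
  sources <- lapply(config$codata, load_codata_source, p = data$p)
  t0 <- proc.time()[["elapsed"]]
  fit <- codapen(data$x, data$y, sources, family = config$family,
                 block_size = config$block_size,
                 n_splits = config$n_splits, seed = config$seed)
  logf("fit done in", round(proc.time()[["elapsed"]] - t0, 2), "s")
  write_fit_report(fit, arts[["report"]])
  written <- c(written, arts[["report"]])
  nms <- data$names %||% paste0("V", seq_len(data$p))
  utils::write.table(
    data.frame(index = seq_len(data$p), name = nms,
               beta = fit$fit$beta, penalty = fit$penalties),
    arts[["coefficients"]], sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, arts[["coefficients"]])
  out <- arts[c("report", "coefficients", "log")]
  if (!is.null(config$alpha)) {
    sp <- sparsify_fit(fit, data, config$alpha)
    write_selection(sp, arts[["selection"]], names = nms)
    written <- c(written, arts[["selection"]])
    logf("sparse fit:", sum(sp$beta != 0), "variables selected at alpha",
         config$alpha)
    out <- arts
  }
  ok <- TRUE
  invisible(as.list(out))
}

sim_schema <- list(
  n = "numeric", p = "numeric", family = "character",
  codata_kind = "character", relation = "character", params = "list",
  noise_sd = "numeric", sparse_frac = "numeric",
  n_replicates = "numeric", seed = "numeric", task = "character",
  models = "character", alpha = "numeric", n_basis = "numeric",
  n_splits = "numeric", outdir = "character")

#' Run a simulation workflow from a design configuration
#'
#' Validates the design, runs the requested benchmark
#' (`task: model_comparison` or `task: selection`) and writes the result
#' tables as TSV to the output directory.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, the list of artefact paths.
#' @export
run_simulate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(sim_schema))
  if (length(unknown) > 0)
    stop("unknown simulation keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$outdir)) stop("missing simulation key: outdir")
  design <- sim_design(
    n = config$n %||% 150L, p = config$p %||% 1000L,
    family = config$family %||% "gaussian",
    codata_kind = config$codata_kind %||% "informative",
    relation = config$relation %||% "linear",
    params = config$params %||% list(),
    noise_sd = config$noise_sd %||% 1,
    sparse_frac = config$sparse_frac %||% 0,
    n_replicates = config$n_replicates %||% 20L,
    seed = config$seed %||% 1L)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  task <- config$task %||% "model_comparison"
  if (task == "model_comparison") {
    res <- run_codata_model_comparison(
      design, models = config$models %||% c("linear", "gam",
                                            "agnostic_ridge"),
      n_basis = as.integer(config$n_basis %||% 20L),
      n_splits = as.integer(config$n_splits %||% 10L))
    paths <- file.path(config$outdir, c("metrics.tsv", "curves.tsv"))
    # wall time is informational and excluded so identical seeds give
    # byte-identical artefacts
    utils::write.table(res$metrics[setdiff(names(res$metrics), "time")],
                       paths[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(res$curves, paths[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (task == "selection") {
    res <- run_selection_comparison(
      design, alpha = config$alpha %||% 0.5,
      n_basis = as.integer(config$n_basis %||% 20L),
      n_splits = as.integer(config$n_splits %||% 10L))
    paths <- file.path(config$outdir, "selection_metrics.tsv")
    utils::write.table(res, paths, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unknown task: ", task)
  invisible(as.list(paths))
}
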