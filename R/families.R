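#' Response families
#'
#' Constructs a response family object holding the canonical link, its
#' inverse, and family-specific likelihood machinery used by the penalised
#' IRLS fitter.  Supported families are `"gaussian"` (identity link),
#' `"binomial"` (logit link) and `"cox"` (log relative hazard; partial
#' likelihood with Breslow tie handling, no intercept).
#'
#' @param name One of `"gaussian"`, `"binomial"`, `"cox"`.
#' @return An object of class `codapen_family` with elements `name`,
#'   `link` and `invlink`.
#' @examples
#' fam <- response_family("binomial")
#' fam$invlink(0)  # 0.5
#' @export
response_family <- function(name = c("gaussian", "binomial", "cox")) {
  name <- match.arg(name)
  fam <- switch(name,
    gaussian = list(
      name = "gaussian",
      link = function(mu) mu,
      invlink = function(eta) eta
    ),
    binomial = list(
      name = "binomial",
      link = function(mu) log(mu / (1 - mu)),
      invlink = function(eta) 1 / (1 + exp(-eta))
    ),
    cox = list(
      name = "cox",
      # canonical scale is the log relative hazard itself
      link = function(mu) log(mu),
      invlink = function(eta) eta
    )
  )
  structure(fam, class = "codapen_family")
}

#' @export
print.codapen_family <- function(x, ...) {
  cat("<codapen_family>", x$name, "\n")
  invisible(x)
}

#' Assemble a dataset for penalised fitting
#'
#' Bundles an observation matrix with its response and validates shapes.
#' For the Cox family the response must be a two-column matrix (or data
#' frame) of positive times and 0/1 event indicators.
#'
#' @param x Numeric matrix, `n` samples by `p` variables; no missing values.
#' @param y Response: numeric vector (gaussian), 0/1 vector (binomial), or
#'   a two-column `(time, event)` matrix (cox).
#' @param family A `codapen_family` or family name.
#' @return A `codapen_data` list with `x`, `y`, `n`, `p`, `family`.
#' @export
codapen_data <- function(x, y, family = "gaussian") {
  if (!inherits(family, "codapen_family")) family <- response_family(family)
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains missing values")
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L || p < 1L) stop("need n >= 2 and p >= 1")
  if (family$name == "cox") {
    y <- as.matrix(y)
    if (ncol(y) != 2L) stop("cox response must be a (time, event) matrix")
    if (anyNA(y)) stop("y contains missing values")
    if (any(y[, 1L] <= 0)) stop("cox times must be positive")
    if (!all(y[, 2L] %in% c(0, 1))) stop("cox events must be 0/1")
    if (nrow(y) != n) stop("nrow(y) != nrow(x)")
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop("y contains missing values")
    if (length(y) != n) stop(sprintf("length(y) is %d but x has %d rows",
                                     length(y), n))
    if (family$name == "binomial" && !all(y %in% c(0, 1)))
      stop("binomial response must be 0/1")
  }
  structure(list(x = x, y = y, n = n, p = p, family = family),
            class = "codapen_data")
}
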