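# Construction of co-data matrices and their smoothing/constraint machinery.

#' Dummy co-data matrix from a group set
#'
#' Encodes a list of (possibly overlapping) variable groups as a p-by-G
#' dummy co-data matrix.  A variable belonging to `m` groups contributes
#' `1/m` to each of its group columns, so every covered variable carries
#' unit total mass across columns.  Variables covered by no group get a
#' dedicated "rest" column, appended only when at least one variable is
#' uncovered.
#'
#' @param groups Named or unnamed list of integer index vectors over `1..p`.
#' @param p Number of variables.
#' @return A p-by-G (or G+1 with rest column) numeric matrix with column
#'   names.
#' @examples
#' z_from_groupset(list(a = c(1, 2), b = c(2, 3)), p = 3)
#' @export
z_from_groupset <- function(groups, p) {
  if (length(groups) == 0L) stop("need at least one group")
  for (g in groups) {
    if (length(g) == 0L) stop("empty group in group set")
    if (any(g < 1L | g > p)) stop("group indices must lie in 1..p")
  }
  G <- length(groups)
  z <- matrix(0, p, G)
  mult <- integer(p)
  for (j in seq_len(G)) mult[groups[[j]]] <- mult[groups[[j]]] + 1L
  for (j in seq_len(G)) z[groups[[j]], j] <- 1 / mult[groups[[j]]]
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(G))
  colnames(z) <- nms
  if (any(mult == 0L)) {
    z <- cbind(z, as.numeric(mult == 0L))
    colnames(z)[G + 1L] <- "rest"
  }
  z
}

#' P-spline basis expansion of a continuous co-data variable
#'
#' Evaluates a B-spline basis of the given degree at the co-data values,
#' with `J - degree` equally spaced knot intervals spanning the observed
#' range and the knot grid extended `degree` intervals beyond each
#' boundary (the p-spline convention).  With equally spaced knots the
#' null space of the second-order difference penalty maps exactly onto
#' affine functions of the co-data, which is what makes heavy smoothing
#' degenerate to the linear co-data model.  Rows sum to one (partition of
#' unity) over the observed range.
#'
#' @param z Length-p numeric co-data column, finite, non-constant.
#' @param n_basis Number of basis functions `J` (default 20, the usual
#'   p-spline richness for a single smooth).
#' @param degree Spline degree (default cubic).
#' @return p-by-J basis matrix with attributes `knots`, `degree`,
#'   `range` so new co-data values can be expanded consistently.
#' @export
z_spline_basis <- function(z, n_basis = 20L, degree = 3L) {
  if (any(!is.finite(z))) stop("co-data values must be finite")
  if (n_basis < degree + 1L) stop("need n_basis >= degree + 1")
  r <- range(z)
  if (r[1] == r[2])
    stop("constant co-data column: a spline basis is degenerate, ",
         "use a linear co-data model instead")
  n_int <- n_basis - degree           # number of interior intervals
  h <- (r[2] - r[1]) / n_int
  knots <- r[1] + h * seq.int(-degree, n_int + degree)
  phi <- splines::splineDesign(knots, z, ord = degree + 1L,
                               outer.ok = FALSE)
  attr(phi, "knots") <- knots
  attr(phi, "degree") <- degree
  attr(phi, "range") <- r
  phi
}

#' Evaluate an existing spline basis at new co-data values
#'
#' @param phi A basis returned by [z_spline_basis()].
#' @param znew New co-data values; clamped to the training range so
#'   boundary evaluation stays well defined.
#' @export
eval_spline_basis <- function(phi, znew) {
  knots <- attr(phi, "knots")
  degree <- attr(phi, "degree")
  r <- attr(phi, "range")
  znew <- pmin(pmax(znew, r[1]), r[2])
  splines::splineDesign(knots, znew, ord = degree + 1L, outer.ok = FALSE)
}

#' Difference penalty matrix for p-splines
#'
#' Returns \eqn{S = D^\top D} with `D` the order-th finite-difference
#' operator on `J` coefficients, the quadratic smoothing penalty on the
#' differences of adjacent spline coefficients.  `S` is symmetric positive
#' semi-definite with a null space of dimension `order` spanned by
#' polynomial coefficient sequences of degree `< order`.
#'
#' @param n_basis Number of spline coefficients `J`.
#' @param order Difference order (default 2, penalising deviation from
#'   linearity).
#' @export
difference_penalty <- function(n_basis, order = 2L) {
  if (order < 1L || order >= n_basis)
    stop("need 1 <= order < n_basis")
  d <- diff(diag(n_basis), differences = order)
  crossprod(d)
}

#' Shape-constraint matrices on spline coefficients
#'
#' Builds the inequality system `M %*% gamma <= b` (with `b = 0`) that
#' encodes shape restrictions on a spline curve through its coefficients:
#' positivity constrains each coefficient to be non-negative, monotonicity
#' the first-order differences, convexity/concavity the second-order
#' differences.  Shapes combine by stacking rows.
#'
#' @param shapes Character subset of `positive`, `monotone_increasing`,
#'   `monotone_decreasing`, `convex`, `concave`.
#' @param n_basis Number of spline coefficients `J`.
#' @return List with `m_ineq` (rows-by-J), `b_ineq` (zeros), and empty
#'   `m_eq`, `b_eq`.
#' @export
shape_constraints <- function(shapes, n_basis) {
  valid <- c("positive", "monotone_increasing", "monotone_decreasing",
             "convex", "concave")
  shapes <- unique(match.arg(shapes, valid, several.ok = TRUE))
  if (all(c("monotone_increasing", "monotone_decreasing") %in% shapes))
    stop("contradictory shapes: increasing and decreasing")
  if (all(c("convex", "concave") %in% shapes))
    stop("contradictory shapes: convex and concave")
  J <- n_basis
  d1 <- diff(diag(J), differences = 1L)
  d2 <- diff(diag(J), differences = 2L)
  m <- NULL
  for (s in shapes) {
    m <- rbind(m, switch(s,
      positive            = -diag(J),
      monotone_increasing = -d1,
      monotone_decreasing = d1,
      convex              = -d2,
      concave             = d2
    ))
  }
  list(m_ineq = m, b_ineq = rep(0, nrow(m)),
       m_eq = matrix(0, 0L, J), b_eq = numeric(0))
}

#' Handle missing values in a raw co-data matrix
#'
#' When missingness is deemed uninformative, missing entries are replaced
#' by the column mean.  When informative, they are set to 0 and one 0/1
#' missingness-indicator column is appended per affected column, so the
#' co-data model can learn a separate effect for the missing variables.
#'
#' @param z_raw p-by-G numeric matrix, possibly with `NA` entries.
#' @param informative Is the missingness itself informative?
#' @export
handle_missing_codata <- function(z_raw, informative = FALSE) {
  z <- as.matrix(z_raw)
  if (!anyNA(z)) return(z)
  nms <- colnames(z)
  if (is.null(nms)) nms <- paste0("z", seq_len(ncol(z)))
  if (any(colSums(!is.na(z)) == 0L))
    stop("co-data column with all values missing")
  if (!informative) {
    for (j in seq_len(ncol(z))) {
      miss <- is.na(z[, j])
      if (any(miss)) z[miss, j] <- mean(z[!miss, j])
    }
    colnames(z) <- nms
    return(z)
  }
  ind <- NULL
  ind_nms <- character(0)
  for (j in seq_len(ncol(z))) {
    miss <- is.na(z[, j])
    if (any(miss)) {
      z[miss, j] <- 0
      ind <- cbind(ind, as.numeric(miss))
      ind_nms <- c(ind_nms, paste0(nms[j], "_missing"))
    }
  }
  out <- cbind(z, ind)
  colnames(out) <- c(nms, ind_nms)
  out
}

#' Declare a co-data source and its co-data model
#'
#' Bundles one co-data matrix with the co-data model used to regress prior
#' variances on it: `linear` uses the columns of `z` as-is; `gam` expands
#' each column in a p-spline basis with a difference penalty; `scam`
#' additionally imposes shape constraints on the spline coefficients.
#'
#' @param z p-by-G co-data matrix (or a length-p vector for a single
#'   continuous co-data variable).
#' @param model `"linear"`, `"gam"` or `"scam"`.
#' @param n_basis,degree,diff_order Spline settings for `gam`/`scam`.
#' @param shapes Shape set for `scam` (see [shape_constraints()]); default
#'   positivity.
#' @param lambda Optional fixed smoothing penalty; if `NULL` it is
#'   estimated by random splits.
#' @param name Optional label used in reports.
#' @return A `codata_source` object: `z`, `model`, and for spline models
#'   `phi` (stacked expansion), `blocks` (column index list per co-data
#'   variable), `s_list`, `constraints`, `lambda`.
#' @export
codata_source <- function(z, model = c("linear", "gam", "scam"),
                          n_basis = 20L, degree = 3L, diff_order = 2L,
                          shapes = "positive", lambda = NULL,
                          name = NULL) {
  model <- match.arg(model)
  z <- as.matrix(z)
  if (anyNA(z)) stop("co-data contains missing values; see handle_missing_codata()")
  src <- list(z = z, model = model, name = name %||% "codata",
              lambda = lambda)
  if (model != "linear") {
    phis <- lapply(seq_len(ncol(z)), function(j)
      z_spline_basis(z[, j], n_basis = n_basis, degree = degree))
    sizes <- vapply(phis, ncol, integer(1))
    ends <- cumsum(sizes)
    src$blocks <- Map(function(e, s) (e - s + 1L):e, ends, sizes)
    src$phi <- do.call(cbind, phis)
    src$phi_bases <- phis
    src$s_list <- lapply(sizes, difference_penalty, order = diff_order)
    if (model == "scam")
      src$constraints <- lapply(sizes, function(J)
        shape_constraints(shapes, J))
    src$shapes <- if (model == "scam") shapes else NULL
  }
  structure(src, class = "codata_source")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codata_source <- function(x, ...) {
  cat("<codata_source>", x$name, ":", ncol(x$z), "co-data variable(s),",
      x$model, "co-data model\n")
  invisible(x)
}
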