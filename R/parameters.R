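#' Parameters of the tumor/T-cell population model
#'
#' Bundles the full parameter vector of the ODE system describing M cancer
#' subpopulations growing logistically under competition and being lysed by
#' active T cells, which in turn become exhausted by the killing process:
#' \deqn{\dot y_i = r_i y_i (1 - \sum_j a_j y_j / K) - d_i y_i - h_i y_i x_A}
#' \deqn{\dot x_A = r_A x_A (1 - (b_A x_A + b_E x_E)/C) - x_A \sum_j l_j y_j}
#' \deqn{\dot x_E = x_A \sum_j l_j y_j - d_E x_E}
#' Rates are per hour; carrying capacities K and C are in cell-index (CI)
#' units, the impedance proxy for adherent cell number.  T cells are in
#' suspension and do not contribute to the measured CI.
#'
#' @param r length-M vector of cancer proliferation rates (1/h).
#' @param d length-M vector of cancer degradation rates (1/h).
#' @param a length-M vector of logistic competition weights (dimensionless,
#'   > 0).
#' @param K carrying capacity of the cancer population (CI units, > 0).
#' @param h length-M vector of cytolysis rates per unit active-T level (1/h
#'   per CI-equivalent).
#' @param l length-M vector of T-cell exhaustion rates per unit cancer level
#'   (1/h per CI unit).
#' @param b_A,b_E logistic weights of active and exhausted T cells
#'   (dimensionless, > 0).
#' @param r_A proliferation rate of active T cells (1/h).
#' @param d_E degradation rate of exhausted T cells (1/h).
#' @param C carrying capacity of the T-cell population (CI-equivalent units,
#'   > 0).
#' @return An object of class `model_parameters` with element `M` (number of
#'   cancer subpopulations) and the fields above.
#' @examples
#' p <- model_parameters(r = 2, d = 1, a = 1, K = 2, h = 0.8, l = 1,
#'                       b_A = 0.5, b_E = 0.5, r_A = 2, d_E = 1, C = 10)
#' p$M
#' @export
model_parameters <- function(r, d, a, K, h, l, b_A, b_E, r_A, d_E, C) {
  M <- length(r)
  if (M < 1L) stop("at least one cancer subpopulation is required (M >= 1)")
  vecs <- list(r = r, d = d, a = a, h = h, l = l)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != M)
      stop(sprintf("field '%s' has length %d but M = %d", nm, length(v), M))
    if (!is.numeric(v) || anyNA(v)) stop(sprintf("field '%s' must be numeric", nm))
    if (any(v < 0)) stop(sprintf("field '%s' must be nonnegative", nm))
  }
  scal <- c(K = K, b_A = b_A, b_E = b_E, r_A = r_A, d_E = d_E, C = C)
  if (anyNA(scal) || !is.numeric(scal)) stop("scalar fields must be numeric")
  if (any(scal[c("r_A", "d_E")] < 0)) stop("r_A and d_E must be nonnegative")
  if (K <= 0 || C <= 0) stop("K and C must be positive")
  if (any(a <= 0)) stop("competition weights a must be positive")
  if (b_A <= 0 || b_E <= 0) stop("logistic weights b_A, b_E must be positive")
  structure(
    list(M = M, r = as.numeric(r), d = as.numeric(d), a = as.numeric(a),
         K = as.numeric(K), h = as.numeric(h), l = as.numeric(l),
         b_A = as.numeric(b_A), b_E = as.numeric(b_E), r_A = as.numeric(r_A),
         d_E = as.numeric(d_E), C = as.numeric(C)),
    class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("Tumor/T-cell model parameters (M = %d cancer subpopulations)\n", x$M))
  fmt <- function(v) paste(formatC(v, digits = 4, format = "g"), collapse = ", ")
  cat(sprintf("  r   = (%s) 1/h\n", fmt(x$r)))
  cat(sprintf("  d   = (%s) 1/h\n", fmt(x$d)))
  cat(sprintf("  a   = (%s)\n", fmt(x$a)))
  cat(sprintf("  K   = %s CI\n", fmt(x$K)))
  cat(sprintf("  h   = (%s) 1/h per CI-eq\n", fmt(x$h)))
  cat(sprintf("  l   = (%s) 1/h per CI\n", fmt(x$l)))
  cat(sprintf("  b_A = %s, b_E = %s\n", fmt(x$b_A), fmt(x$b_E)))
  cat(sprintf("  r_A = %s 1/h, d_E = %s 1/h, C = %s CI-eq\n",
              fmt(x$r_A), fmt(x$d_E), fmt(x$C)))
  invisible(x)
}

# Flat encoding consumed by the compiled integrator.
as_theta <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  c(params$M, params$r, params$d, params$a, params$K, params$h, params$l,
    params$b_A, params$b_E, params$r_A, params$d_E, params$C)
}

#' Search ranges for the model parameters
#'
#' Closed intervals `[lo, hi]` bounding each named parameter during fitting
#' and random initialisation.  The defaults are the standard wide boxes used
#' for this model family: rates `r`, `d`, `r_A`, `d_E` in \[0, 50\] 1/h,
#' logistic weights `a`, `b` in \[1e-3, 1\], interaction rates `l`, `h` in
#' \[0, 5\], carrying capacities `K`, `C` in \[1, 100\] CI units.
#'
#' @param ... named length-2 numeric overrides, e.g. `K = c(1, 10)`.  Valid
#'   names: `r`, `d`, `a`, `l`, `h`, `b`, `r_A`, `d_E`, `K`, `C`.
#' @return A named list of `c(lo, hi)` intervals, class `parameter_ranges`.
#' @examples
#' default_parameter_ranges()$K
#' parameter_ranges(K = c(1, 10))$K
#' @export
parameter_ranges <- function(...) {
  rg <- list(r = c(0, 50), d = c(0, 50), a = c(1e-3, 1), l = c(0, 5),
             h = c(0, 5), b = c(1e-3, 1), r_A = c(0, 50), d_E = c(0, 50),
             K = c(1, 100), C = c(1, 100))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(rg)) stop(sprintf("unknown parameter range '%s'", nm))
    v <- as.numeric(dots[[nm]])
    if (length(v) != 2L || anyNA(v) || v[1] > v[2])
      stop(sprintf("range '%s' must be c(lo, hi) with lo <= hi", nm))
    rg[[nm]] <- v
  }
  structure(rg, class = "parameter_ranges")
}

#' @rdname parameter_ranges
#' @export
default_parameter_ranges <- function() parameter_ranges()

# Interval for one flat component name like "r_2", "b_A", "K".
range_for <- function(ranges, name) {
  base <- sub("_[0-9]+$", "", name)
  if (base %in% c("b_A", "b_E")) base <- "b"
  if (!base %in% names(ranges)) stop(sprintf("no range for parameter '%s'", name))
  ranges[[base]]
}

#' Check that parameters lie inside their search ranges
#'
#' @param params a [model_parameters()] object.
#' @param ranges a [parameter_ranges()] object.
#' @return `TRUE` invisibly; errors naming the offending field otherwise.
#' @export
validate_parameters <- function(params, ranges = default_parameter_ranges()) {
  stopifnot(inherits(params, "model_parameters"))
  chk <- function(val, key, nm) {
    rg <- ranges[[key]]
    if (any(val < rg[1] - 1e-12) || any(val > rg[2] + 1e-12))
      stop(sprintf("parameter '%s' outside range [%g, %g]", nm, rg[1], rg[2]))
  }
  chk(params$r, "r", "r"); chk(params$d, "d", "d"); chk(params$a, "a", "a")
  chk(params$h, "h", "h"); chk(params$l, "l", "l")
  chk(params$b_A, "b", "b_A"); chk(params$b_E, "b", "b_E")
  chk(params$r_A, "r_A", "r_A"); chk(params$d_E, "d_E", "d_E")
  chk(params$K, "K", "K"); chk(params$C, "C", "C")
  invisible(TRUE)
}

#' Serialize model parameters to and from JSON
#'
#' The flat JSON document records `M` and every field by name, so parameter
#' sets round-trip losslessly between analyses.
#'
#' @param params a [model_parameters()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `params_to_json()`: the JSON string (invisibly when written to a
#'   file).  `params_from_json()`: a [model_parameters()] object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname params_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  p <- model_parameters(r = x$r, d = x$d, a = x$a, K = x$K, h = x$h, l = x$l,
                        b_A = x$b_A, b_E = x$b_E, r_A = x$r_A, d_E = x$d_E,
                        C = x$C)
  if (!is.null(x$M) && x$M != p$M) stop("JSON field M inconsistent with vector lengths")
  p
}

#' Reference fitted parameter sets for HAP1 cells
#'
#' Best-fit parameter sets (M = 3 cancer subpopulations) for parental HAP1
#' cells and their FASN-knockout derivatives, obtained from macroevolutionary
#' fits of the model to real-time impedance killing-assay data.  Useful as
#' realistic magnitudes for forward simulation and as truth anchors for
#' synthetic benchmarks.  The knockout line shows a similar net growth rate
#' but higher cytolysis rates, reflecting its increased sensitivity to
#' T-cell killing.
#'
#' @param line `"parental"` (FASN wild-type) or `"fasn_ko"`.
#' @return A [model_parameters()] object with `M = 3`.
#' @examples
#' hap1_reference_parameters("fasn_ko")$h
#' @export
hap1_reference_parameters <- function(line = c("parental", "fasn_ko")) {
  line <- match.arg(line)
  if (line == "parental") {
    model_parameters(
      r = c(2.701, 2.342, 4.462), d = c(2.141, 1.757, 3.834),
      a = c(0.834, 0.036, 0.677), K = 1.794,
      h = c(0.642, 0.356, 0.084), l = c(3.845, 3.403, 1.437),
      b_A = 0.548, b_E = 0.378, r_A = 23.300, d_E = 29.383, C = 6.334)
  } else {
    model_parameters(
      r = c(4.424, 6.162, 10.005), d = c(3.975, 5.922, 9.659),
      a = c(0.175, 0.980, 0.138), K = 2.037,
      h = c(0.955, 4.212, 3.677), l = c(3.875, 1.637, 1.597),
      b_A = 0.169, b_E = 0.469, r_A = 2.671, d_E = 35.676, C = 72.179)
  }
}
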