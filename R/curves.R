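# Concentration-response curves: relative risk as a function of annual-mean
# PM2.5 concentration.
#
# Closed-form shapes (linear, log-linear, log-log) are parameterized by the
# relative risk per 10 ug/m3 (RR10) and a counterfactual cut-off C0 below
# which RR = 1. All three shapes satisfy RR(C0) = 1 and RR(C0 + 10) = RR10.
# Tabulated curves (GEMM / MR-BRT style) are piecewise-linear interpolations
# of a fitted RR grid with an intrinsic cut-off.

CURVE_SHAPES <- c("linear", "loglinear", "loglog", "tabulated")

#' Relative risk per 10 ug/m3 with its 95% CI
#'
#' @param central Central RR per 10 ug/m3 increment.
#' @param lo,hi 2.5% and 97.5% CI endpoints. Default to `central` when a
#'   source reports no interval.
#' @return An object of class `relative_risk10`.
#' @export
relative_risk10 <- function(central, lo = central, hi = central) {
  vals <- c(lo = lo, central = central, hi = hi)
  if (anyNA(vals) || any(vals <= 0)) {
    stop("relative risks must be positive", call. = FALSE)
  }
  if (!(lo <= central && central <= hi)) {
    stop("require lo <= central <= hi", call. = FALSE)
  }
  if (lo < 1 && central >= 1) {
    # protective lower endpoints occur in real meta-analyses; keep them,
    # the PAF engine rejects RR < 1 only where the algebra would break
    NULL
  }
  structure(list(central = central, lo = lo, hi = hi),
            class = "relative_risk10")
}

rr10_endpoint <- function(rr10, endpoint = c("central", "lo", "hi")) {
  endpoint <- match.arg(endpoint)
  if (inherits(rr10, "relative_risk10")) rr10[[endpoint]] else as.numeric(rr10)
}

check_conc <- function(C) {
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
}

#' Linear concentration-response curve
#'
#' \eqn{RR(C) = 1 + (RR_{10} - 1)/10 \cdot (C - C_0)} for `C > C0`, and 1 at
#' or below the cut-off.
#'
#' @param rr10 RR per 10 ug/m3 (scalar or [relative_risk10()]).
#' @param C Concentration(s) in ug/m3; vectorized.
#' @param C0 Cut-off (counterfactual) concentration in ug/m3.
#' @param endpoint Which CI endpoint of `rr10` to use.
#' @return Relative risk(s), same length as `C`.
#' @export
rr_linear <- function(rr10, C, C0 = 0, endpoint = "central") {
  r <- rr10_endpoint(rr10, endpoint)
  if (r <= 0) stop("rr10 must be positive", call. = FALSE)
  check_conc(C); check_conc(C0)
  ifelse(C <= C0, 1, 1 + (r - 1) / 10 * (C - C0))
}

#' Log-linear concentration-response curve
#'
#' \eqn{RR(C) = e^{\beta (C - C_0)}} with \eqn{\beta = \ln(RR_{10})/10} above
#' the cut-off, 1 at or below it.
#'
#' @inheritParams rr_linear
#' @return Relative risk(s).
#' @export
rr_loglinear <- function(rr10, C, C0 = 0, endpoint = "central") {
  r <- rr10_endpoint(rr10, endpoint)
  if (r <= 0) stop("rr10 must be positive", call. = FALSE)
  check_conc(C); check_conc(C0)
  beta <- log(r) / 10
  ifelse(C <= C0, 1, exp(beta * (C - C0)))
}

#' Log-log (supra-linear) concentration-response curve
#'
#' \eqn{RR(C) = [(C + 1)/(C_0 + 1)]^{\beta}} with
#' \eqn{\beta = \ln(RR_{10}) / [\ln(10 + C_0 + 1) - \ln(C_0 + 1)]} above the
#' cut-off, 1 at or below it. Rises steeply at low concentrations and
#' flattens at higher ones; anchored so that \eqn{RR(C_0 + 10) = RR_{10}}
#' for every cut-off.
#'
#' @inheritParams rr_linear
#' @return Relative risk(s).
#' @export
rr_loglog <- function(rr10, C, C0 = 0, endpoint = "central") {
  r <- rr10_endpoint(rr10, endpoint)
  if (r <= 0) stop("rr10 must be positive", call. = FALSE)
  check_conc(C); check_conc(C0)
  beta <- log(r) / (log(10 + C0 + 1) - log(C0 + 1))
  ifelse(C <= C0, 1, ((C + 1) / (C0 + 1))^beta)
}

#' Tabulated non-linear concentration-response curve
#'
#' Container for fitted RR curves supplied as a concentration grid (GEMM /
#' MR-BRT style): central, low and high RR at each grid point plus an
#' intrinsic cut-off below which RR = 1.
#'
#' @param grid Strictly ascending concentrations in ug/m3 (>= 2 points).
#' @param rr,rr_lo,rr_hi Relative risks at each grid point; must satisfy
#'   `rr_lo <= rr <= rr_hi` pointwise and all be positive.
#' @param cutoff Intrinsic cut-off in ug/m3 (default 2.4, the GEMM value).
#' @param cause Cause-of-death label the curve applies to.
#' @param source_label Free-text provenance label.
#' @return An object of class `tabulated_curve`.
#' @export
tabulated_curve <- function(grid, rr, rr_lo = rr, rr_hi = rr,
                            cutoff = 2.4, cause = "all-cause",
                            source_label = "") {
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("grid must be strictly ascending with >= 2 points", call. = FALSE)
  }
  if (any(c(rr, rr_lo, rr_hi) <= 0)) stop("all RR must be > 0", call. = FALSE)
  if (any(rr_lo > rr) || any(rr > rr_hi)) {
    stop("require rr_lo <= rr <= rr_hi pointwise", call. = FALSE)
  }
  if (!is.finite(cutoff) || cutoff < 0) {
    stop("cutoff must be finite and >= 0", call. = FALSE)
  }
  structure(list(grid = grid, rr = as.numeric(rr), rr_lo = as.numeric(rr_lo),
                 rr_hi = as.numeric(rr_hi), cutoff = cutoff, cause = cause,
                 source_label = source_label),
            class = "tabulated_curve")
}

#' Load a tabulated curve from CSV
#'
#' Expects columns `concentration_ugm3`, `rr`, `rr_lo`, `rr_hi`. Curve
#' metadata (`cause`, `cutoff_ugm3`, `source_label`) may come from a JSON
#' sidecar file `<path>.json` or be passed directly; arguments win over the
#' sidecar.
#'
#' @param path CSV path.
#' @param cutoff,cause,source_label Optional metadata overrides.
#' @return A `tabulated_curve`.
#' @export
load_tabulated_curve <- function(path, cutoff = NULL, cause = NULL,
                                 source_label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("curve file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_ugm3", "rr")
  if (!all(need %in% names(df))) {
    stop("curve table needs columns concentration_ugm3 and rr", call. = FALSE)
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  val <- function(arg, key, default) {
    if (!is.null(arg)) arg else if (!is.null(meta[[key]])) meta[[key]] else default
  }
  tabulated_curve(
    df$concentration_ugm3, df$rr,
    rr_lo = if ("rr_lo" %in% names(df)) df$rr_lo else df$rr,
    rr_hi = if ("rr_hi" %in% names(df)) df$rr_hi else df$rr,
    cutoff = as.numeric(val(cutoff, "cutoff_ugm3", 2.4)),
    cause = as.character(val(cause, "cause", "all-cause")),
    source_label = as.character(val(source_label, "source_label", "")))
}

#' Write a tabulated curve to CSV (with JSON metadata sidecar)
#' @param curve A `tabulated_curve`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tabulated_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(concentration_ugm3 = curve$grid, rr = curve$rr,
               rr_lo = curve$rr_lo, rr_hi = curve$rr_hi),
    path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(cause = curve$cause, cutoff_ugm3 = curve$cutoff,
         source_label = curve$source_label),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Evaluate a tabulated curve
#'
#' Piecewise-linear interpolation on the grid, clamped to the last grid
#' value beyond the grid, and RR = 1 at or below the curve's cut-off. When
#' the cut-off was overridden above a grid region, RR is re-clamped to 1
#' below the override and left unchanged above it.
#'
#' @param curve A `tabulated_curve`.
#' @param C Concentration(s), vectorized.
#' @param endpoint `"central"`, `"lo"` or `"hi"`.
#' @param cutoff Optional cut-off override in ug/m3.
#' @return Relative risk(s).
#' @export
rr_tabulated <- function(curve, C, endpoint = c("central", "lo", "hi"),
                         cutoff = NULL) {
  stopifnot(inherits(curve, "tabulated_curve"))
  endpoint <- match.arg(endpoint)
  check_conc(C)
  y <- switch(endpoint, central = curve$rr, lo = curve$rr_lo, hi = curve$rr_hi)
  c0 <- if (is.null(cutoff)) curve$cutoff else cutoff
  out <- stats::approx(curve$grid, y, xout = C, rule = 2)$y
  out[C <= c0] <- 1
  out
}

#' Curve specification: shape + parameters + cut-off
#'
#' A declarative description of one concentration-response curve, dispatched
#' by [make_curve()] to the shape-specific evaluator. Exactly one of `rr10`
#' (closed-form shapes) or `table` (tabulated shape) must be given.
#'
#' @param shape One of `"linear"`, `"loglinear"`, `"loglog"`, `"tabulated"`.
#' @param rr10 A [relative_risk10()] or scalar RR per 10 ug/m3.
#' @param cutoff Cut-off in ug/m3 (>= 0). For tabulated curves this
#'   overrides the intrinsic cut-off when given.
#' @param table A [tabulated_curve()] (tabulated shape only).
#' @param cause Cause-of-death label.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(shape, rr10 = NULL, cutoff = 0, table = NULL,
                       cause = "all-cause") {
  shape <- match.arg(shape, CURVE_SHAPES)
  if (shape == "tabulated") {
    if (is.null(table) || !inherits(table, "tabulated_curve")) {
      stop("tabulated shape needs a tabulated_curve in `table`", call. = FALSE)
    }
    if (!is.null(rr10)) stop("tabulated shape takes no rr10", call. = FALSE)
    if (missing(cutoff)) cutoff <- table$cutoff
  } else {
    if (is.null(rr10)) stop(sprintf("%s shape needs rr10", shape), call. = FALSE)
    if (!inherits(rr10, "relative_risk10")) rr10 <- relative_risk10(rr10)
    if (rr10$central < 1) {
      stop("protective central RR (< 1): no supported curve is protective",
           call. = FALSE)
    }
  }
  if (!is.finite(cutoff) || cutoff < 0) {
    stop("cutoff must be finite and >= 0", call. = FALSE)
  }
  structure(list(shape = shape, rr10 = rr10, cutoff = cutoff, table = table,
                 cause = cause),
            class = "curve_spec")
}

#' @export
print.curve_spec <- function(x, ...) {
  if (x$shape == "tabulated") {
    cat(sprintf("curve_spec: tabulated [%s], cutoff %g ug/m3, cause %s\n",
                x$table$source_label, x$cutoff, x$cause))
  } else {
    cat(sprintf("curve_spec: %s, RR10 %g (%g-%g), cutoff %g ug/m3, cause %s\n",
                x$shape, x$rr10$central, x$rr10$lo, x$rr10$hi, x$cutoff,
                x$cause))
  }
  invisible(x)
}

#' Build a concentration -> RR evaluator from a curve spec
#'
#' @param spec A [curve_spec()].
#' @param endpoint CI endpoint selector: `"central"`, `"lo"` or `"hi"`.
#' @return A vectorized function `f(C)` returning relative risks.
#' @export
make_curve <- function(spec, endpoint = c("central", "lo", "hi")) {
  stopifnot(inherits(spec, "curve_spec"))
  endpoint <- match.arg(endpoint)
  switch(spec$shape,
    linear    = function(C) rr_linear(spec$rr10, C, spec$cutoff, endpoint),
    loglinear = function(C) rr_loglinear(spec$rr10, C, spec$cutoff, endpoint),
    loglog    = function(C) rr_loglog(spec$rr10, C, spec$cutoff, endpoint),
    tabulated = function(C) rr_tabulated(spec$table, C, endpoint,
                                         cutoff = spec$cutoff),
    stop(sprintf("unknown curve shape: %s", spec$shape), call. = FALSE))
}
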