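# Binned population exposure distributions for annual-mean PM2.5.
#
# A distribution is a set of contiguous, ascending, half-open concentration
# bins [lower, upper) each carrying the fraction of the population exposed
# within that interval (EF_i). Bins are nominally 1 ug/m3 wide but the engine
# never assumes width 1. The representative concentration of a bin is its
# midpoint.

EXPOSURE_VARIANTS <- c("central", "lo95", "hi95")

#' Construct a binned PM2.5 exposure distribution
#'
#' Builds and validates an exposure distribution from bin edges and
#' population fractions (or raw population counts, which are normalized to
#' fractions while the raw total is preserved for count reporting).
#'
#' @param lower,upper Numeric vectors of bin edges in ug/m3. Bins must be
#'   half-open `[lower, upper)`, contiguous, non-overlapping and ascending.
#' @param fraction Non-negative population fractions per bin. If they do not
#'   sum to 1 they are renormalized; a deviation larger than `1e-6` triggers
#'   a warning.
#' @param variant One of `"central"`, `"lo95"`, `"hi95"`, labelling which
#'   confidence-interval variant of the distribution this is.
#' @param total_population Optional raw population total behind the
#'   fractions; retained as metadata.
#' @return An object of class `exposure_distribution`: a list with elements
#'   `bins` (data.frame `lower`, `upper`, `fraction`), `variant` and
#'   `total_population`.
#' @seealso [load_exposure()], [pwc()], [shift_distribution()],
#'   [collapse_to_pwc()]
#' @examples
#' d <- exposure_distribution(c(0, 1), c(1, 2), c(0.5, 0.5))
#' pwc(d)
#' @export
exposure_distribution <- function(lower, upper, fraction,
                                  variant = "central",
                                  total_population = NULL) {
  if (length(lower) == 0L) {
    stop("exposure distribution needs at least one bin", call. = FALSE)
  }
  if (length(upper) != length(lower) || length(fraction) != length(lower)) {
    stop("lower, upper and fraction must have equal length", call. = FALSE)
  }
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  fraction <- as.numeric(fraction)
  if (anyNA(lower) || anyNA(upper) || anyNA(fraction) ||
      any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bin edges and fractions must be finite numbers", call. = FALSE)
  }
  variant <- match.arg(variant, EXPOSURE_VARIANTS)

  ord <- order(lower)
  lower <- lower[ord]; upper <- upper[ord]; fraction <- fraction[ord]

  if (any(lower < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(upper <= lower)) {
    bad <- which(upper <= lower)[1L]
    stop(sprintf("bin %d has upper <= lower (%g <= %g)",
                 bad, upper[bad], lower[bad]), call. = FALSE)
  }
  if (any(fraction < 0)) {
    stop("negative population fraction", call. = FALSE)
  }
  n <- length(lower)
  if (n > 1L) {
    gap <- which(abs(lower[-1L] - upper[-n]) > 1e-9)
    if (length(gap)) {
      i <- gap[1L]
      stop(sprintf(
        "bins must be contiguous and non-overlapping: bin %d ends at %g but bin %d starts at %g",
        i, upper[i], i + 1L, lower[i + 1L]), call. = FALSE)
    }
    # snap edges exactly so downstream arithmetic sees no float drift
    lower[-1L] <- upper[-n]
  }
  tot <- sum(fraction)
  if (tot <= 0) {
    stop("all population fractions are zero", call. = FALSE)
  }
  if (abs(tot - 1) > 1e-6) {
    warning(sprintf("fractions sum to %.9g; renormalizing to 1", tot),
            call. = FALSE)
  }
  fraction <- fraction / tot

  structure(
    list(bins = data.frame(lower = lower, upper = upper, fraction = fraction),
         variant = variant,
         total_population = total_population),
    class = "exposure_distribution")
}

#' @export
print.exposure_distribution <- function(x, ...) {
  cat(sprintf("PM2.5 exposure distribution (%s): %d bins over [%g, %g) ug/m3\n",
              x$variant, nrow(x$bins), min(x$bins$lower), max(x$bins$upper)))
  cat(sprintf("  population-weighted concentration: %.3f ug/m3\n", pwc(x)))
  if (!is.null(x$total_population)) {
    cat(sprintf("  population total: %g\n", x$total_population))
  }
  invisible(x)
}

#' Load an exposure distribution from tabular input
#'
#' Reads a CSV file (or an already-parsed data.frame) with columns
#' `lower_ugm3`, `upper_ugm3` and either `fraction` or `population`, plus an
#' optional `variant` column (`central`/`lo95`/`hi95`). Plain `lower`/`upper`
#' column names are also accepted. When several variants are present a named
#' list of distributions is returned.
#'
#' @param x Path to a CSV file, or a data.frame.
#' @param variant If the table has no `variant` column, the label to assign.
#' @return An `exposure_distribution`, or a named list of them (one per
#'   variant present in the table).
#' @export
load_exposure <- function(x, variant = "central") {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("exposure file not found: %s", x),
                              call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  names(df) <- tolower(names(df))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(nm)
    NULL
  }
  lo_col <- pick("lower_ugm3", "lower")
  up_col <- pick("upper_ugm3", "upper")
  fr_col <- pick("fraction", "population")
  if (is.null(lo_col) || is.null(up_col) || is.null(fr_col)) {
    stop("exposure table needs columns lower_ugm3, upper_ugm3 and fraction (or population)",
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("exposure table has no rows", call. = FALSE)

  build <- function(sub, label) {
    tot <- if (fr_col == "population") sum(as.numeric(sub[[fr_col]])) else NULL
    exposure_distribution(sub[[lo_col]], sub[[up_col]], sub[[fr_col]],
                          variant = label, total_population = tot)
  }
  if ("variant" %in% names(df)) {
    labs <- unique(df$variant)
    out <- lapply(labs, function(v) build(df[df$variant == v, , drop = FALSE], v))
    names(out) <- labs
    if (length(out) == 1L) out[[1L]] else out
  } else {
    build(df, variant)
  }
}

#' Write an exposure distribution (or variant set) to CSV
#'
#' @param dist An `exposure_distribution` or a named list of variants.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure <- function(dist, path) {
  one <- function(d) {
    data.frame(lower_ugm3 = d$bins$lower, upper_ugm3 = d$bins$upper,
               fraction = d$bins$fraction, variant = d$variant)
  }
  df <- if (inherits(dist, "exposure_distribution")) one(dist) else
    do.call(rbind, lapply(dist, one))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Representative concentration of each bin (midpoint)
#' @param dist An `exposure_distribution`.
#' @return Numeric vector of bin midpoints in ug/m3.
#' @export
bin_midpoints <- function(dist) {
  stopifnot(inherits(dist, "exposure_distribution"))
  (dist$bins$lower + dist$bins$upper) / 2
}

#' Population-weighted mean concentration (PWC)
#'
#' The mean exposure weighted by population fraction,
#' \eqn{\mathrm{PWC} = \sum_i C_i \, EF_i}, with \eqn{C_i} the bin midpoint.
#'
#' @param dist An `exposure_distribution`.
#' @return PWC in ug/m3 (scalar).
#' @export
pwc <- function(dist) {
  sum(bin_midpoints(dist) * dist$bins$fraction)
}

#' Shift an exposure distribution to higher concentrations
#'
#' Adds `delta` to every bin edge while keeping the population fraction in
#' each interval constant, so the shape is preserved and
#' `pwc(shift_distribution(d, delta)) == pwc(d) + delta` exactly. Used to
#' construct higher-exposure scenarios (e.g. shifting a PWC-5 distribution
#' to PWCs of 10, 15 or 30 ug/m3).
#'
#' @param dist An `exposure_distribution`.
#' @param delta Non-negative concentration increment in ug/m3.
#' @return The shifted `exposure_distribution`.
#' @export
shift_distribution <- function(dist, delta) {
  stopifnot(inherits(dist, "exposure_distribution"))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("delta must be a single non-negative concentration", call. = FALSE)
  }
  out <- dist
  out$bins$lower <- dist$bins$lower + delta
  out$bins$upper <- dist$bins$upper + delta
  out
}

#' Collapse a distribution to its population-weighted mean
#'
#' Returns the degenerate single-bin distribution of width one centred on
#' the PWC, with fraction 1. Feeding it to the attribution engine reproduces
#' the PWC shortcut \eqn{\mathrm{PAF} = (RR_{PWC} - 1)/RR_{PWC}}: with no
#' cut-off it matches the full-distribution result for a linear curve, but
#' with a cut-off above the PWC it attributes nothing even when part of the
#' population is exposed above the cut-off.
#'
#' @param dist An `exposure_distribution`.
#' @return A single-bin `exposure_distribution` with the same PWC.
#' @export
collapse_to_pwc <- function(dist) {
  m <- pwc(dist)
  exposure_distribution(m - 0.5, m + 0.5, 1,
                        variant = dist$variant,
                        total_population = dist$total_population)
}
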