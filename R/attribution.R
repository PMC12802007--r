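# Population attributable fraction and attributable burden.
#
# The burden of a cause attributable to PM2.5 is AB = PAF x BoD, where BoD
# is the population burden (deaths, YLL, YLD or DALY) and
#
#   PAF = (sum_i RR_i EF_i - 1) / (sum_i RR_i EF_i)
#
# over the exposure bins i, with RR evaluated at bin midpoints. When the
# exposure is summarized by its population-weighted mean the expression
# collapses to PAF = (RR_PWC - 1)/RR_PWC.

BOD_MEASURES <- c("deaths", "YLL", "YLD", "DALY")
BOD_CAUSES <- c("all-cause", "NCD+LRI", "IHD", "stroke", "COPD", "ALRI",
                "lung cancer", "diabetes-2")

#' Load and validate a cause x measure burden-of-disease table
#'
#' Expects columns `cause`, `measure` (deaths/YLL/YLD/DALY), `value`, and
#' optionally `lo`, `hi` (95% CI; may be missing, e.g. registry sources
#' publish no intervals) and `source`.
#'
#' @param x CSV path or data.frame.
#' @return A data.frame of class `health_table` with columns `cause`,
#'   `measure`, `value`, `lo`, `hi`, `source`.
#' @export
load_health_table <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("health file not found: %s", x),
                              call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  need <- c("cause", "measure", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("health table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"lo" %in% names(df)) df$lo <- NA_real_
  if (!"hi" %in% names(df)) df$hi <- NA_real_
  if (!"source" %in% names(df)) df$source <- ""
  bad <- setdiff(unique(df$measure), BOD_MEASURES)
  if (length(bad)) {
    stop(sprintf("unknown measure(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$value < 0, na.rm = TRUE)) {
    stop("negative burden value", call. = FALSE)
  }
  ok_ci <- is.na(df$lo) | is.na(df$hi) |
    (df$lo >= 0 & df$lo <= df$value & df$value <= df$hi)
  if (!all(ok_ci)) {
    stop("require 0 <= lo <= value <= hi where a CI is present", call. = FALSE)
  }
  # cross-check DALY = YLL + YLD where all three are present (rounded inputs)
  for (cz in unique(df$cause)) {
    sub <- df[df$cause == cz, ]
    if (all(c("DALY", "YLL", "YLD") %in% sub$measure)) {
      d <- sub$value[sub$measure == "DALY"][1L]
      s <- sub$value[sub$measure == "YLL"][1L] + sub$value[sub$measure == "YLD"][1L]
      if (abs(d - s) > 0.5) {
        warning(sprintf("cause %s: DALY (%g) != YLL + YLD (%g)", cz, d, s),
                call. = FALSE)
      }
    }
  }
  df <- df[, c("cause", "measure", "value", "lo", "hi", "source")]
  class(df) <- c("health_table", "data.frame")
  df
}

#' Extract one cause x measure record from a health table
#' @param table A `health_table`.
#' @param cause,measure Row selectors.
#' @return A one-row data.frame.
#' @export
health_record <- function(table, cause, measure) {
  row <- table[table$cause == cause & table$measure == measure, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no health record for cause '%s', measure '%s'",
                 cause, measure), call. = FALSE)
  }
  row[1L, , drop = FALSE]
}

#' Population attributable fraction from a full exposure distribution
#'
#' Evaluates the curve at every bin midpoint and applies
#' \eqn{\mathrm{PAF} = (\sum RR_i EF_i - 1)/(\sum RR_i EF_i)}.
#'
#' @param dist An `exposure_distribution`.
#' @param curve A vectorized concentration -> RR function (from
#'   [make_curve()]) or a [curve_spec()].
#' @return The PAF, in `[0, 1)` when all RR >= 1.
#' @export
paf_distribution <- function(dist, curve) {
  stopifnot(inherits(dist, "exposure_distribution"))
  if (inherits(curve, "curve_spec")) curve <- make_curve(curve)
  rr <- curve(bin_midpoints(dist))
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("curve returned a non-positive or non-finite relative risk",
         call. = FALSE)
  }
  s <- sum(rr * dist$bins$fraction)
  (s - 1) / s
}

#' Population attributable fraction from a single relative risk
#'
#' The PWC shortcut \eqn{\mathrm{PAF} = (RR_{PWC} - 1)/RR_{PWC}}.
#'
#' @param rr_pwc Relative risk evaluated at the population-weighted mean
#'   concentration.
#' @return The PAF.
#' @export
paf_pwc <- function(rr_pwc) {
  if (any(!is.finite(rr_pwc)) || any(rr_pwc <= 0)) {
    stop("rr_pwc must be positive and finite", call. = FALSE)
  }
  (rr_pwc - 1) / rr_pwc
}

#' Attributable burden for one cause x measure record
#'
#' @param paf Population attributable fraction in `[0, 1)`.
#' @param record One-row health record (see [health_record()]), or a list
#'   with at least `cause`, `measure`, `value`.
#' @return A one-row data.frame: `cause`, `measure`, `paf`, `attributable`,
#'   `lo`, `hi`, `uncertainty_source`.
#' @export
attributable_burden <- function(paf, record) {
  if (!is.finite(paf) || paf < 0 || paf >= 1) {
    stop("paf must lie in [0, 1)", call. = FALSE)
  }
  if (is.na(record$value) || record$value < 0) {
    stop("burden value must be non-negative", call. = FALSE)
  }
  data.frame(cause = record$cause, measure = record$measure, paf = paf,
             attributable = paf * record$value,
             lo = NA_real_, hi = NA_real_,
             uncertainty_source = "none",
             stringsAsFactors = FALSE)
}

#' Attributable burden per cause, plus a sum row
#'
#' Applies each cause's own curve to the shared exposure distribution and
#' multiplies the resulting PAF into that cause's burden. Causes present in
#' the health table but absent from the curve set are skipped with a notice;
#' a curve whose cause is missing from the table is an error.
#'
#' @param dist An `exposure_distribution`.
#' @param curves Named list of [curve_spec()]s, keyed by cause.
#' @param health A `health_table`.
#' @param measure One of deaths/YLL/YLD/DALY.
#' @param endpoint CI endpoint for the curves.
#' @return A data.frame with one row per cause and a final `"sum"` row.
#' @export
attributable_by_cause <- function(dist, curves, health,
                                  measure = "deaths",
                                  endpoint = "central") {
  measure <- match.arg(measure, BOD_MEASURES)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    stop("curves must be a named list keyed by cause", call. = FALSE)
  }
  skipped <- setdiff(unique(health$cause[health$measure == measure]),
                     names(curves))
  if (length(skipped)) {
    message("causes in health table without a curve (skipped): ",
            paste(skipped, collapse = ", "))
  }
  rows <- lapply(names(curves), function(cz) {
    rec <- tryCatch(health_record(health, cz, measure), error = function(e) {
      stop(sprintf("cause '%s' has a curve but no %s record in the health table",
                   cz, measure), call. = FALSE)
    })
    p <- paf_distribution(dist, make_curve(curves[[cz]], endpoint))
    attributable_burden(p, rec)
  })
  out <- do.call(rbind, rows)
  sum_row <- data.frame(cause = "sum", measure = measure, paf = NA_real_,
                        attributable = sum(out$attributable),
                        lo = NA_real_, hi = NA_real_,
                        uncertainty_source = "none",
                        stringsAsFactors = FALSE)
  rbind(out, sum_row)
}

#' Combine YLL and YLD attribution results into a DALY result
#'
#' Attributable DALY = attributable YLL + attributable YLD (computed with
#' the same mortality-based PAF); also reports the YLL share of the DALYs,
#' the mortality-driven fraction.
#'
#' @param yll,yld One-row attribution results (from
#'   [attributable_burden()]) for the same cause.
#' @return A one-row data.frame with `measure = "DALY"` and an extra
#'   `yll_share` column (fraction in `[0, 1]`; `NA` when YLL + YLD = 0).
#' @export
daly_decomposition <- function(yll, yld) {
  if (!identical(yll$cause, yld$cause)) {
    stop(sprintf("cause mismatch: '%s' vs '%s'", yll$cause, yld$cause),
         call. = FALSE)
  }
  if (!identical(yll$measure, "YLL") || !identical(yld$measure, "YLD")) {
    stop("expected a YLL result and a YLD result", call. = FALSE)
  }
  tot <- yll$attributable + yld$attributable
  share <- if (tot > 0) yll$attributable / tot else NA_real_
  data.frame(cause = yll$cause, measure = "DALY", paf = yll$paf,
             attributable = tot, lo = NA_real_, hi = NA_real_,
             uncertainty_source = "none", yll_share = share,
             stringsAsFactors = FALSE)
}

#' Round attributable counts for reporting
#'
#' Internally attributable counts stay unrounded; human-readable reports
#' round deaths to whole counts, half away from zero.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
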