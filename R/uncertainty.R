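# Endpoint-substitution uncertainty and the scenario grid.
#
# Uncertainty in the attributable burden is quantified by re-running the
# whole pipeline with the 2.5% / 97.5% endpoint of exactly one input
# category (relative risk, exposure distribution, or health data)
# substituted for its central estimate. One category is varied at a time; a
# combined Monte-Carlo propagation is deliberately not implemented.

UNCERTAINTY_SOURCES <- c("rr", "exposure", "health", "none")

#' Define a scenario configuration
#'
#' Bundles the concrete inputs of one pipeline run: an exposure distribution
#' (optionally with lo95/hi95 variants), a curve spec (or a named list of
#' curve specs keyed by cause), a health table, the measure, and the
#' methodological switches (PWC pathway, shift).
#'
#' @param id Scenario identifier (user-supplied string).
#' @param exposure An `exposure_distribution`, or a named list with elements
#'   `central` and optionally `lo95`, `hi95`.
#' @param curve A [curve_spec()] for an all-cause run, or a named list of
#'   curve specs keyed by cause for a cause-specific run.
#' @param health A `health_table` (see [load_health_table()]).
#' @param measure One of deaths/YLL/YLD/DALY.
#' @param use_pwc If `TRUE`, collapse the exposure distribution to its
#'   population-weighted mean before computing the PAF (the PWC shortcut).
#' @param shift_delta Non-negative shift (ug/m3) applied to the exposure
#'   distribution before anything else, for higher-exposure scenarios.
#' @param uncertainty Which input category's 95% CI to propagate for this
#'   scenario: `"rr"`, `"exposure"`, `"health"` or `"none"`.
#' @return An object of class `bod_scenario`.
#' @export
bod_scenario <- function(id, exposure, curve, health, measure = "deaths",
                         use_pwc = FALSE, shift_delta = 0,
                         uncertainty = "rr") {
  measure <- match.arg(measure, BOD_MEASURES)
  uncertainty <- match.arg(uncertainty, UNCERTAINTY_SOURCES)
  if (inherits(exposure, "exposure_distribution")) {
    exposure <- list(central = exposure)
  }
  if (!is.list(exposure) || is.null(exposure$central)) {
    stop(sprintf("scenario '%s': exposure needs at least a central distribution",
                 id), call. = FALSE)
  }
  if (inherits(curve, "curve_spec")) {
    curve <- stats::setNames(list(curve), curve$cause)
  }
  if (!all(vapply(curve, inherits, logical(1), "curve_spec"))) {
    stop(sprintf("scenario '%s': curve must be curve_spec(s)", id),
         call. = FALSE)
  }
  structure(list(id = as.character(id), exposure = exposure, curve = curve,
                 health = health, measure = measure, use_pwc = use_pwc,
                 shift_delta = shift_delta, uncertainty = uncertainty),
            class = "bod_scenario")
}

# Run one scenario with a chosen endpoint for each input category.
# exposure_variant: central / lo95 / hi95; curve_endpoint, health_endpoint:
# central / lo / hi. Returns the total attributable burden (sum over causes).
eval_scenario <- function(sc, exposure_variant = "central",
                          curve_endpoint = "central",
                          health_endpoint = "central") {
  dist <- sc$exposure[[exposure_variant]]
  if (is.null(dist)) {
    stop(sprintf("scenario '%s': no %s exposure variant", sc$id,
                 exposure_variant), call. = FALSE)
  }
  if (sc$shift_delta > 0) dist <- shift_distribution(dist, sc$shift_delta)
  if (isTRUE(sc$use_pwc)) dist <- collapse_to_pwc(dist)
  hcol <- switch(health_endpoint, central = "value", lo = "lo", hi = "hi")
  total <- 0
  for (cz in names(sc$curve)) {
    rec <- health_record(sc$health, cz, sc$measure)
    val <- rec[[hcol]]
    if (is.na(val)) {
      stop(sprintf("no %s endpoint for cause '%s'", health_endpoint, cz),
           call. = FALSE)
    }
    p <- paf_distribution(dist, make_curve(sc$curve[[cz]], curve_endpoint))
    total <- total + p * val
  }
  total
}

#' Propagate one input category's 95% CI by endpoint substitution
#'
#' Re-runs the full pipeline twice with the chosen category's lo then hi
#' endpoint substituted for the central estimate (everything else held at
#' its central value) and returns the resulting attributable-burden pair,
#' ordered.
#'
#' @param scenario A [bod_scenario()].
#' @param which `"rr"`, `"exposure"` or `"health"`.
#' @return A list: `lo`, `hi` (ordered attributable values) and `available`.
#'   When the category carries no interval (e.g. registry health data with
#'   no published CI, or an exposure input without lo95/hi95 variants) the
#'   result is `available = FALSE` with a `reason` — not a silent zero.
#' @export
propagate_endpoint <- function(scenario, which = c("rr", "exposure", "health")) {
  which <- match.arg(which)
  run <- function(ev = "central", ce = "central", he = "central") {
    eval_scenario(scenario, ev, ce, he)
  }
  pair <- switch(which,
    rr = {
      r <- scenario$curve[[1L]]$rr10
      if (scenario$curve[[1L]]$shape != "tabulated" &&
          !is.null(r) && r$lo == r$central && r$hi == r$central) {
        return(list(lo = NA_real_, hi = NA_real_, available = FALSE,
                    reason = "relative risk has no interval"))
      }
      c(run(ce = "lo"), run(ce = "hi"))
    },
    exposure = {
      if (is.null(scenario$exposure$lo95) || is.null(scenario$exposure$hi95)) {
        return(list(lo = NA_real_, hi = NA_real_, available = FALSE,
                    reason = "exposure input has no lo95/hi95 variants"))
      }
      c(run(ev = "lo95"), run(ev = "hi95"))
    },
    health = {
      ok <- tryCatch(c(run(he = "lo"), run(he = "hi")), error = function(e) NULL)
      if (is.null(ok)) {
        return(list(lo = NA_real_, hi = NA_real_, available = FALSE,
                    reason = "no interval available for the health data"))
      }
      ok
    })
  list(lo = min(pair), hi = max(pair), available = TRUE)
}

#' Sum per-cause uncertainty intervals componentwise
#'
#' The summed interval for a set of causes is `(sum lo_i, sum hi_i)` — the
#' componentwise convention, not a variance-based combination.
#'
#' @param intervals A data.frame with columns `lo`, `hi` and optionally
#'   `measure` (must be a single measure if present).
#' @return A list with `lo` and `hi`.
#' @export
sum_cause_intervals <- function(intervals) {
  if ("measure" %in% names(intervals) &&
      length(unique(intervals$measure)) > 1L) {
    stop("cannot sum intervals across different measures", call. = FALSE)
  }
  list(lo = sum(intervals$lo), hi = sum(intervals$hi))
}

#' Percent change of an estimate versus a reference
#'
#' @param estimate,reference Attributable-burden values; `reference` > 0.
#' @return Signed percent, `(estimate - reference)/reference * 100`; `NA`
#'   when the reference is zero.
#' @export
percent_change <- function(estimate, reference) {
  ifelse(reference == 0, NA_real_, (estimate - reference) / reference * 100)
}

#' Run a grid of scenarios and tabulate percent changes vs the reference
#'
#' Evaluates every scenario deterministically (central estimate plus the
#' endpoint-substitution interval for its declared uncertainty category) and
#' reports each one's percent change against the reference scenario's
#' central estimate. Output rows follow the grid order.
#'
#' @param scenarios List of [bod_scenario()]s with unique ids.
#' @param reference_id Id of the reference scenario (must occur exactly once).
#' @return A data.frame ledger: `scenario_id`, `measure`, `attributable`,
#'   `lo`, `hi`, `uncertainty_source`, `pct_change_vs_reference`.
#' @export
run_scenario_grid <- function(scenarios, reference_id) {
  if (length(scenarios) == 0L) stop("empty scenario grid", call. = FALSE)
  ids <- vapply(scenarios, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate scenario id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (sum(ids == reference_id) != 1L) {
    stop(sprintf("reference scenario '%s' must occur exactly once",
                 reference_id), call. = FALSE)
  }
  central <- vapply(scenarios, eval_scenario, numeric(1))
  refval <- central[ids == reference_id]
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    iv <- if (sc$uncertainty == "none") {
      list(lo = NA_real_, hi = NA_real_, available = FALSE)
    } else {
      propagate_endpoint(sc, sc$uncertainty)
    }
    data.frame(
      scenario_id = sc$id, measure = sc$measure,
      attributable = central[i],
      lo = iv$lo, hi = iv$hi,
      uncertainty_source = if (isTRUE(iv$available)) sc$uncertainty else "none",
      pct_change_vs_reference = percent_change(central[i], refval),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
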