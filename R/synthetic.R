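# Synthetic inputs with the statistical structure the analysis assumes:
# right-skewed unimodal exposure distributions binned at 1 ug/m3 with a
# target population-weighted mean, GBD-style cause-of-death tables, and
# supra-linear tabulated risk curves. Everything is deterministic under a
# seed so the whole pipeline is testable without external downloads.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic PM2.5 exposure distribution
#'
#' Draws a right-skewed unimodal (gamma) population of annual-mean
#' exposures, rescales it so the sample mean hits the target exactly before
#' binning, and discretizes to fixed-width bins. The achieved PWC of the
#' binned distribution (computed from bin midpoints) lands within a
#' half-bin-width of the target. Confidence-interval variants are produced
#' by scaling all concentrations by fixed factors (defaults 0.8 / 1.2,
#' mirroring a 4.0-6.0 ug/m3 interval around a mean of 5.0).
#'
#' @param target_pwc Target population-weighted mean concentration, ug/m3.
#' @param dispersion Coefficient of variation of the underlying gamma
#'   exposure; default 0.5 gives a clear right skew with the mode below the
#'   mean.
#' @param bin_width Bin width in ug/m3 (default 1).
#' @param max_conc Upper edge of the binning range; must exceed the target.
#' @param seed Integer seed; fixes the output exactly.
#' @param n Number of simulated individuals.
#' @param ci_scale Length-2 multiplicative factors for the lo95/hi95
#'   concentration variants.
#' @return A named list of `exposure_distribution`s: `central`, `lo95`,
#'   `hi95`.
#' @export
generate_exposure <- function(target_pwc = 5.0, dispersion = 0.5,
                              bin_width = 1, max_conc = 40, seed = 1,
                              n = 100000, ci_scale = c(0.8, 1.2)) {
  if (target_pwc <= 0) stop("target_pwc must be > 0", call. = FALSE)
  if (max_conc <= target_pwc) {
    stop("max_conc must exceed target_pwc: target unreachable", call. = FALSE)
  }
  shape <- 1 / dispersion^2
  raw <- with_seed(seed, stats::rgamma(n, shape = shape,
                                       scale = target_pwc / shape))
  raw <- raw * (target_pwc / mean(raw))  # hit the target mean exactly
  bin_one <- function(x, variant) {
    x <- pmin(x, max_conc - bin_width / 2)  # clamp the far tail into range
    edges <- seq(0, max_conc, by = bin_width)
    counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1L)
    keep <- seq_len(max(which(counts > 0)))
    exposure_distribution(edges[keep], edges[keep + 1L],
                          counts[keep] / length(x),
                          variant = variant, total_population = length(x))
  }
  list(central = bin_one(raw, "central"),
       lo95 = bin_one(raw * ci_scale[1L], "lo95"),
       hi95 = bin_one(raw * ci_scale[2L], "hi95"))
}

DEFAULT_CAUSE_FRACTIONS <- c(
  "IHD" = 0.120, "stroke" = 0.070, "COPD" = 0.060, "ALRI" = 0.050,
  "lung cancer" = 0.055, "diabetes-2" = 0.015)

#' Generate a synthetic cause-of-death / burden table
#'
#' Emulates a GBD-style table: all-cause, NCD+LRI (the all-cause proxy) and
#' six specific causes, each with deaths, YLL, YLD and DALY. Per-cause
#' deaths are fixed fractions of the all-cause total (jittered slightly
#' under the seed), YLL = deaths x `yll_per_death`, YLD = YLL x
#' `yld_to_yll`, and DALY = YLL + YLD by construction. CI endpoints are
#' `value * (1 -/+ ci_halfwidth)`; the registry variant omits them
#' (national mortality registries typically publish no intervals).
#'
#' @param allcause_deaths All-cause death count scale. The default 37,650
#'   makes reference-configuration runs produce burden numbers of the same
#'   magnitude as a small high-income country; it is a convenience, not
#'   real registry data.
#' @param cause_fractions Named fractions of all-cause deaths for the six
#'   specific causes; must each lie in (0,1) and sum to < 1.
#' @param ncd_lri_fraction NCD+LRI share of all-cause deaths.
#' @param yll_per_death Years of life lost per death.
#' @param yld_to_yll Ratio of YLD to YLL (morbidity share).
#' @param ci_halfwidth Relative CI half-width.
#' @param seed Integer seed for the per-cause jitter.
#' @param source One of `"synthetic-gbd"` (with CIs) or
#'   `"synthetic-registry"` (deaths only, no CIs).
#' @return A `health_table`.
#' @export
generate_health_table <- function(allcause_deaths = 37650,
                                  cause_fractions = DEFAULT_CAUSE_FRACTIONS,
                                  ncd_lri_fraction = 0.88,
                                  yll_per_death = 12,
                                  yld_to_yll = 0.35,
                                  ci_halfwidth = 0.1,
                                  seed = 1,
                                  source = c("synthetic-gbd",
                                             "synthetic-registry")) {
  source <- match.arg(source)
  if (any(cause_fractions <= 0) || any(cause_fractions >= 1) ||
      sum(cause_fractions) >= 1) {
    stop("cause fractions must lie in (0,1) and sum to < 1", call. = FALSE)
  }
  if (ncd_lri_fraction <= 0 || ncd_lri_fraction >= 1) {
    stop("ncd_lri_fraction must lie in (0,1)", call. = FALSE)
  }
  jit <- with_seed(seed, stats::rlnorm(length(cause_fractions),
                                       meanlog = 0, sdlog = 0.05))
  deaths <- c("all-cause" = allcause_deaths,
              "NCD+LRI" = allcause_deaths * ncd_lri_fraction,
              allcause_deaths * cause_fractions * jit)
  rows <- lapply(names(deaths), function(cz) {
    d <- unname(deaths[cz])
    yll <- d * yll_per_death
    yld <- yll * yld_to_yll
    vals <- c(deaths = d, YLL = yll, YLD = yld, DALY = yll + yld)
    data.frame(cause = cz, measure = names(vals), value = unname(vals),
               lo = if (source == "synthetic-gbd")
                 unname(vals) * (1 - ci_halfwidth) else NA_real_,
               hi = if (source == "synthetic-gbd")
                 unname(vals) * (1 + ci_halfwidth) else NA_real_,
               source = source, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  load_health_table(tab)
}

#' Generate a synthetic tabulated (GEMM / MR-BRT style) risk curve
#'
#' Builds a monotone non-decreasing RR grid with RR = 1 at the cut-off,
#' passing through the supplied anchors, using power-law segments
#' `r_j + (r_{j+1} - r_j) * t^p`. A `"gemm-like"` curve (`p = 0.35`) bends
#' up steeply at low concentrations; an `"mrbrt-like"` curve (`p = 0.75`) is
#' closer to linear at low exposure. Beyond the last anchor the curve is
#' flat (tabulated evaluation clamps there anyway). Lo/hi bands scale the
#' excess risk by `1 -/+ halfwidth`.
#'
#' @param kind `"gemm-like"` or `"mrbrt-like"`.
#' @param cause Cause label.
#' @param anchor_conc,anchor_rr Anchor concentrations (ascending, all above
#'   the cut-off) and the RRs there (positive, non-decreasing).
#' @param cutoff Intrinsic cut-off in ug/m3 (default 2.4).
#' @param halfwidth Relative half-width of the lo/hi excess-risk band.
#' @param grid_step Grid spacing in ug/m3.
#' @param grid_max Upper end of the grid.
#' @return A `tabulated_curve`.
#' @export
generate_tabulated_curve <- function(kind = c("gemm-like", "mrbrt-like"),
                                     cause = "NCD+LRI",
                                     anchor_conc = 20, anchor_rr = 1.25,
                                     cutoff = 2.4, halfwidth = 0.3,
                                     grid_step = 1, grid_max = 100) {
  kind <- match.arg(kind)
  if (length(anchor_conc) != length(anchor_rr)) {
    stop("anchor_conc and anchor_rr must have equal length", call. = FALSE)
  }
  if (any(anchor_rr <= 0) || any(diff(anchor_rr) < 0)) {
    stop("anchor RRs must be positive and non-decreasing", call. = FALSE)
  }
  if (any(diff(anchor_conc) <= 0) || any(anchor_conc <= cutoff)) {
    stop("anchor concentrations must be ascending and above the cutoff",
         call. = FALSE)
  }
  p <- if (kind == "gemm-like") 0.35 else 0.75
  kx <- c(cutoff, anchor_conc)
  ky <- c(1, anchor_rr)
  evalc <- function(C) {
    vapply(C, function(x) {
      if (x <= cutoff) return(1)
      if (x >= kx[length(kx)]) return(ky[length(ky)])
      j <- max(which(kx <= x))
      t <- (x - kx[j]) / (kx[j + 1L] - kx[j])
      ky[j] + (ky[j + 1L] - ky[j]) * t^p
    }, numeric(1))
  }
  grid <- sort(unique(c(seq(cutoff, grid_max, by = grid_step),
                        anchor_conc, grid_max)))
  rr <- evalc(grid)
  tabulated_curve(grid, rr,
                  rr_lo = 1 + (rr - 1) * (1 - halfwidth),
                  rr_hi = 1 + (rr - 1) * (1 + halfwidth),
                  cutoff = cutoff, cause = cause,
                  source_label = paste0("synthetic-", kind))
}

#' Write a full synthetic dataset to a directory
#'
#' Writes the three CSV families consumed by the pipeline: an exposure
#' distribution with CI variants (`exposure.csv`), GBD-style and
#' registry-style health tables (`health_gbd.csv`, `health_registry.csv`),
#' and two tabulated curves (`curve_gemm.csv`, `curve_mrbrt.csv`, each with
#' a JSON metadata sidecar).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param target_pwc Target PWC for the exposure distribution.
#' @param allcause_deaths Scale of the health table.
#' @return Invisibly, a list with the generated objects and the achieved
#'   PWC.
#' @export
write_synthetic_dataset <- function(dir, seed = 1, target_pwc = 5.0,
                                    allcause_deaths = 37650) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expo <- generate_exposure(target_pwc = target_pwc, seed = seed)
  write_exposure(expo, file.path(dir, "exposure.csv"))
  gbd <- generate_health_table(allcause_deaths = allcause_deaths, seed = seed)
  utils::write.csv(gbd, file.path(dir, "health_gbd.csv"),
                   row.names = FALSE, quote = FALSE)
  reg <- generate_health_table(allcause_deaths = allcause_deaths, seed = seed,
                               source = "synthetic-registry")
  utils::write.csv(reg, file.path(dir, "health_registry.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tabulated_curve(generate_tabulated_curve("gemm-like"),
                        file.path(dir, "curve_gemm.csv"))
  write_tabulated_curve(generate_tabulated_curve("mrbrt-like"),
                        file.path(dir, "curve_mrbrt.csv"))
  invisible(list(exposure = expo, health_gbd = gbd, health_registry = reg,
                 achieved_pwc = pwc(expo$central)))
}
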