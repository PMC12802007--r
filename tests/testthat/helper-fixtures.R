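# Shared fixtures, all built in code.

# Unit-width bins 0..(n-1) with given fractions.
unit_bins <- function(fractions, start = 0) {
  n <- length(fractions)
  exposure_distribution(start + seq_len(n) - 1, start + seq_len(n), fractions)
}

# Degenerate distribution: all mass in one unit bin centred on `conc`.
point_dist <- function(conc) {
  exposure_distribution(conc - 0.5, conc + 0.5, 1)
}

# Random contiguous unit-bin distribution under a local seed.
random_dist <- function(seed, nbins = 50, start = 0) {
  f <- withr::with_seed(seed, stats::runif(nbins))
  unit_bins(f / sum(f), start = start)
}
# withr is not a hard dependency of the package; fall back to base RNG scope.
if (!requireNamespace("withr", quietly = TRUE)) {
  random_dist <- function(seed, nbins = 50, start = 0) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    f <- stats::runif(nbins)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    unit_bins(f / sum(f), start = start)
  }
}

# Independent scalar-loop oracle for the distribution PAF (never vectorized).
paf_oracle <- function(dist, curve_fun) {
  s <- 0
  for (i in seq_len(nrow(dist$bins))) {
    mid <- (dist$bins$lower[i] + dist$bins$upper[i]) / 2
    s <- s + curve_fun(mid) * dist$bins$fraction[i]
  }
  (s - 1) / s
}

# Minimal health table: five specific causes with 100 deaths each plus a
# larger all-cause row.
tiny_health <- function() {
  causes <- c("IHD", "stroke", "COPD", "lung cancer", "diabetes-2")
  load_health_table(data.frame(
    cause = c("all-cause", causes),
    measure = "deaths",
    value = c(1000, rep(100, 5)),
    lo = c(900, rep(90, 5)),
    hi = c(1100, rep(110, 5)),
    source = "fixture"))
}

ref_curve <- function(cutoff = 0) {
  curve_spec("linear", rr10 = relative_risk10(1.08, 1.06, 1.09),
             cutoff = cutoff)
}
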