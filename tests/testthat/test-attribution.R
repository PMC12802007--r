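test_that("PAF formulas reproduce hand-derived values", {
  # degenerate distribution at 5.0, linear RR10 1.08, no cut-off:
  # sum RR*EF = 1.04, PAF = 0.04/1.04
  expect_equal(paf_distribution(point_dist(5), ref_curve()),
               0.04 / 1.04, tolerance = 1e-12)
  expect_equal(paf_pwc(1.04), 0.04 / 1.04, tolerance = 1e-12)
  expect_equal(paf_pwc(1.0), 0)
  expect_equal(paf_pwc(1.24), 0.24 / 1.24, tolerance = 1e-12)
  expect_error(paf_pwc(0), "positive")

  # two bins at RR 1.0 and 1.076 with equal fractions: PAF = 0.038/1.038
  d2 <- unit_bins(c(0.5, 0, 0, 0, 0, 0, 0, 0, 0, 0.5))
  curve2 <- function(C) ifelse(C < 1, 1, 1 + 0.008 * C)
  expect_equal(paf_distribution(d2, curve2), 0.038 / 1.038,
               tolerance = 1e-12)

  # null association: cut-off above every concentration
  d <- random_dist(11, nbins = 20)
  expect_equal(paf_distribution(d, ref_curve(cutoff = 25)), 0)
})

test_that("engine PAF matches the independent scalar-loop oracle", {
  for (seed in 1:10) {
    d <- random_dist(seed)
    for (spec in list(ref_curve(), ref_curve(2.4),
                      curve_spec("loglog", rr10 = 1.08, cutoff = 2),
                      curve_spec("loglinear", rr10 = 1.17))) {
      f <- make_curve(spec)
      expect_equal(paf_distribution(d, spec), paf_oracle(d, f),
                   tolerance = 1e-12)
    }
  }
})

test_that("PWC pathway equals the full distribution for linear, no cut-off", {
  spec <- ref_curve()
  f <- make_curve(spec)
  for (seed in 1:20) {
    d <- random_dist(seed)
    expect_equal(paf_distribution(d, spec), paf_pwc(f(pwc(d))),
                 tolerance = 1e-12)
    # and collapse_to_pwc() reproduces the shortcut through the engine
    expect_equal(paf_distribution(collapse_to_pwc(d), spec),
                 paf_pwc(f(pwc(d))), tolerance = 1e-12)
  }
  # but with a cut-off above the PWC the collapsed pathway attributes nothing
  d <- random_dist(1, nbins = 12)  # PWC near 5-6, mass up to 12
  stopifnot(pwc(d) < 6, max(d$bins$upper) > 6)
  expect_gt(paf_distribution(d, ref_curve(6)), 0)
  expect_equal(paf_distribution(collapse_to_pwc(d), ref_curve(6)), 0)
})

test_that("Jensen: concave log-log gives distribution PAF <= PWC PAF", {
  spec <- curve_spec("loglog", rr10 = 1.08, cutoff = 0)
  f <- make_curve(spec)
  for (seed in 1:20) {
    d <- random_dist(seed, nbins = 30, start = 1)  # wholly above C0 = 0
    expect_lte(paf_distribution(d, spec), paf_pwc(f(pwc(d))) + 1e-12)
  }
})

test_that("PAF is monotone in rr10, cut-off and shift", {
  d <- random_dist(5)
  pafs_rr <- vapply(c(1.02, 1.06, 1.08, 1.14, 1.17),
                    function(r) paf_distribution(d, curve_spec("linear", rr10 = r)),
                    numeric(1))
  expect_true(all(diff(pafs_rr) > 0))
  pafs_c0 <- vapply(c(0, 2, 4, 5, 6),
                    function(c0) paf_distribution(d, ref_curve(c0)),
                    numeric(1))
  expect_true(all(diff(pafs_c0) <= 1e-15))
  pafs_sh <- vapply(c(0, 5, 10, 25), function(del)
    paf_distribution(shift_distribution(d, del), ref_curve(2.4)), numeric(1))
  expect_true(all(diff(pafs_sh) > 0))
  # zero law: cut-off at/above the maximum concentration
  expect_equal(paf_distribution(d, ref_curve(max(d$bins$upper))), 0)
})

test_that("attributable burden scales the record and sums by cause", {
  h <- tiny_health()
  r <- attributable_burden(0.1, health_record(h, "all-cause", "deaths"))
  expect_equal(r$attributable, 100)
  expect_equal(attributable_burden(0, health_record(h, "IHD", "deaths"))$attributable, 0)
  expect_error(attributable_burden(1.2, health_record(h, "IHD", "deaths")),
               "\\[0, 1\\)")

  # five causes sharing a curve: per-cause equal, sum row totals them,
  # and the disease-specific sum stays below the all-cause estimate
  specs <- stats::setNames(
    replicate(5, ref_curve(), simplify = FALSE),
    c("IHD", "stroke", "COPD", "lung cancer", "diabetes-2"))
  d <- point_dist(5)
  suppressMessages(res <- attributable_by_cause(d, specs, h, "deaths"))
  expect_equal(nrow(res), 6L)
  expect_equal(res$attributable[res$cause == "sum"],
               sum(res$attributable[res$cause != "sum"]))
  allc <- attributable_burden(paf_distribution(d, ref_curve()),
                              health_record(h, "all-cause", "deaths"))
  expect_lt(res$attributable[res$cause == "sum"], allc$attributable)
  # single-cause set reduces to attributable_burden
  suppressMessages(one <- attributable_by_cause(d, specs["IHD"], h, "deaths"))
  expect_equal(one$attributable[1L],
               attributable_burden(paf_distribution(d, ref_curve()),
                                   health_record(h, "IHD", "deaths"))$attributable)
  # a curve whose cause is absent from the table names the cause
  expect_error(
    suppressMessages(attributable_by_cause(d, stats::setNames(list(ref_curve()), "ALRI"),
                                           h, "deaths")),
    "ALRI")
})

test_that("DALY decomposition adds YLL and YLD and reports the YLL share", {
  mk <- function(measure, value, paf = 0.05) {
    attributable_burden(paf, data.frame(cause = "IHD", measure = measure,
                                        value = value))
  }
  d <- daly_decomposition(mk("YLL", 1500), mk("YLD", 500))
  expect_equal(d$attributable, 0.05 * 2000)
  expect_equal(d$yll_share, 0.75)
  expect_equal(daly_decomposition(mk("YLL", 100), mk("YLD", 0))$yll_share, 1)
  expect_true(is.na(daly_decomposition(mk("YLL", 0), mk("YLD", 0))$yll_share))
  # same PAF on YLL and YLD equals PAF x (YLL + YLD)
  expect_equal(d$attributable, 0.05 * (1500 + 500), tolerance = 1e-12)
  bad <- mk("YLD", 500); bad$cause <- "stroke"
  expect_error(daly_decomposition(mk("YLL", 100), bad), "mismatch")
})

test_that("health table loader validates structure and CIs", {
  expect_error(load_health_table(data.frame(cause = "x", value = 1)),
               "missing column")
  expect_error(load_health_table(data.frame(cause = "x", measure = "cases",
                                            value = 1)),
               "unknown measure")
  expect_error(load_health_table(data.frame(cause = "x", measure = "deaths",
                                            value = 10, lo = 12, hi = 15)),
               "lo <= value <= hi")
  expect_warning(load_health_table(data.frame(
    cause = "x", measure = c("YLL", "YLD", "DALY"),
    value = c(100, 50, 200))), "DALY")
})
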