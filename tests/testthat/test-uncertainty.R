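make_ref_scenario <- function(id = "reference", curve = ref_curve(),
                              exposure = NULL, health = tiny_health(),
                              ...) {
  if (is.null(exposure)) {
    exposure <- list(central = point_dist(5), lo95 = point_dist(4),
                     hi95 = point_dist(6))
  }
  bod_scenario(id, exposure, curve, health, ...)
}

test_that("endpoint substitution brackets the central estimate and orders the pair", {
  sc <- make_ref_scenario()
  central <- pm25bod:::eval_scenario(sc)
  for (w in c("rr", "exposure", "health")) {
    iv <- propagate_endpoint(sc, w)
    expect_true(iv$available)
    expect_lte(iv$lo, central)
    expect_gte(iv$hi, central)
    expect_lte(iv$lo, iv$hi)
  }
})

test_that("categories without a CI yield an explicit no-interval result", {
  reg <- tiny_health()
  reg$lo <- NA_real_; reg$hi <- NA_real_  # registry style: no intervals
  sc <- make_ref_scenario(health = reg)
  iv <- propagate_endpoint(sc, "health")
  expect_false(iv$available)
  expect_match(iv$reason, "no interval")
  sc2 <- make_ref_scenario(exposure = list(central = point_dist(5)))
  iv2 <- propagate_endpoint(sc2, "exposure")
  expect_false(iv2$available)
  sc3 <- make_ref_scenario(curve = curve_spec("linear", rr10 = 1.08))
  iv3 <- propagate_endpoint(sc3, "rr")
  expect_false(iv3$available)
})

test_that("sum_cause_intervals is componentwise and measure-safe", {
  iv <- sum_cause_intervals(data.frame(lo = c(1, 2), hi = c(3, 4)))
  expect_equal(iv, list(lo = 3, hi = 7))
  one <- sum_cause_intervals(data.frame(lo = 5, hi = 9))
  expect_equal(one, list(lo = 5, hi = 9))
  degen <- sum_cause_intervals(data.frame(lo = c(2, 3), hi = c(2, 3)))
  expect_equal(degen$lo, degen$hi)
  expect_error(
    sum_cause_intervals(data.frame(lo = 1, hi = 2,
                                   measure = c("deaths", "YLL"),
                                   stringsAsFactors = FALSE)),
    "measures")
})

test_that("percent_change handles identity, zero and the reference", {
  expect_equal(percent_change(104, 104), 0)
  expect_equal(percent_change(0, 50), -100)
  expect_true(is.na(percent_change(10, 0)))
  expect_equal(percent_change(2, 1), 100)
})

test_that("the scenario grid reproduces closed-form percent changes", {
  h <- tiny_health()
  expo <- point_dist(5)
  grid <- list(
    make_ref_scenario("reference", exposure = expo, health = h),
    make_ref_scenario("rr117",
                      curve = curve_spec("linear", rr10 = 1.17),
                      exposure = expo, health = h),
    make_ref_scenario("cutoff2-pwc30", curve = ref_curve(2),
                      exposure = expo, health = h, shift_delta = 25),
    make_ref_scenario("nocut-pwc30", curve = ref_curve(),
                      exposure = expo, health = h, shift_delta = 25),
    make_ref_scenario("duplicate-of-reference", exposure = expo, health = h))
  ledger <- run_scenario_grid(grid, "reference")
  expect_equal(nrow(ledger), 5L)
  expect_equal(ledger$scenario_id, vapply(grid, function(s) s$id, character(1)))
  ref_row <- ledger[ledger$scenario_id == "reference", ]
  expect_equal(ref_row$pct_change_vs_reference, 0)
  expect_equal(ledger$pct_change_vs_reference[
    ledger$scenario_id == "duplicate-of-reference"], 0)
  # RR 1.17 vs 1.08 at PWC 5: PAF ratio (0.085/1.085)/(0.04/1.04)
  expect_equal(ledger$pct_change_vs_reference[ledger$scenario_id == "rr117"],
               ((0.085 / 1.085) / (0.04 / 1.04) - 1) * 100, tolerance = 1e-9)
  # cut-off 2 at PWC 30, relative to no-cut-off at PWC 30: about -5%
  pct_cut <- percent_change(
    ledger$attributable[ledger$scenario_id == "cutoff2-pwc30"],
    ledger$attributable[ledger$scenario_id == "nocut-pwc30"])
  expect_equal(pct_cut, ((0.224 / 1.224) / (0.24 / 1.24) - 1) * 100,
               tolerance = 1e-9)

  # independent percent-change oracle from the raw outputs
  refval <- ledger$attributable[ledger$scenario_id == "reference"]
  expect_equal(ledger$pct_change_vs_reference,
               (ledger$attributable - refval) / refval * 100,
               tolerance = 1e-9)

  # determinism: re-running the same grid is identical
  expect_identical(ledger, run_scenario_grid(grid, "reference"))

  # structural errors
  expect_error(run_scenario_grid(list(), "reference"), "empty")
  expect_error(run_scenario_grid(grid, "nope"), "exactly once")
  expect_error(run_scenario_grid(c(grid, grid[1]), "reference"), "duplicate")
})
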