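test_that("utility accrual matches the closed form on an event-free horizon", {
  # alive exactly 10 years at baseline utility, undiscounted
  p <- unclass(survival_toy_params(0, terminal_age = 85, discount = 0))
  p <- validate_parameters(p)
  res <- run_strategy("riva", p)
  expect_equal(res$ly_undiscounted, 10, tolerance = 1e-9)
  expect_equal(res$qaly_undiscounted, 0.779 * 10, tolerance = 1e-9)
  expect_equal(res$qaly_discounted, res$qaly_undiscounted, tolerance = 1e-12)
  # VKA arm carries the treatment disutility while on first-line therapy
  p$persistence$disc_first_cycle <- list(riva = 0, vka = 0)
  p$persistence$disc_subsequent <- list(riva = 0, vka = 0)
  p <- validate_parameters(p)
  res_vka <- run_strategy("vka", p)
  expect_equal(res_vka$qaly_undiscounted, 0.779 * 0.95 * 10, tolerance = 1e-9)
})

test_that("zero costs zero every cost component and leave QALYs unchanged", {
  p0 <- make_fixture("zero_costs")
  res0 <- run_strategy("riva", p0)
  expect_identical(res0$cost_total, 0)
  expect_identical(res0$cost_acquisition, 0)
  expect_identical(res0$cost_monitoring, 0)
  expect_identical(res0$cost_events, 0)
  res <- run_strategy("riva", base_params())
  expect_equal(res0$qaly_discounted, res$qaly_discounted, tolerance = 1e-12)
})

test_that("cost decomposition sums to the total", {
  for (strategy in c("riva", "vka")) {
    res <- run_strategy(strategy, base_params())
    expect_equal(res$cost_total,
                 res$cost_acquisition + res$cost_monitoring + res$cost_events,
                 tolerance = 0.01)
  }
})

test_that("raising one unit cost weakly raises that arm's total and leaves QALYs alone", {
  base <- run_strategy("vka", base_params())
  p <- unclass(base_params())
  p$costs$acute$mi <- p$costs$acute$mi * 2
  p <- validate_parameters(p)
  up <- run_strategy("vka", p)
  expect_gt(up$cost_total, base$cost_total)
  expect_equal(up$cost_events - base$cost_events,
               up$cost_total - base$cost_total, tolerance = 1e-9)
  expect_equal(up$qaly_discounted, base$qaly_discounted, tolerance = 1e-12)
})

test_that("zero discount makes discounted and undiscounted quantities equal", {
  p <- unclass(base_params())
  p$settings$discount_rate_annual <- 0
  p <- validate_parameters(p)
  res <- run_strategy("riva", p)
  expect_equal(res$qaly_discounted, res$qaly_undiscounted, tolerance = 1e-12)
  expect_equal(res$ly_discounted, res$ly_undiscounted, tolerance = 1e-12)
})

test_that("discounted quantities never exceed undiscounted ones", {
  res <- run_strategy("vka", base_params())
  expect_lte(res$qaly_discounted, res$qaly_undiscounted)
  expect_lte(res$ly_discounted, res$ly_undiscounted)
})

test_that("a null treatment effect with equalized costs makes the arms identical", {
  p <- make_fixture("null_effect")
  riva <- run_strategy("riva", p)
  vka <- run_strategy("vka", p)
  for (f in c("qaly_discounted", "ly_discounted", "cost_total",
              "cost_acquisition", "cost_monitoring", "cost_events",
              "expected_strokes", "expected_bleeds"))
    expect_equal(riva[[f]], vka[[f]], tolerance = 1e-9)
  inc <- incremental_analysis(riva, vka)
  expect_equal(inc$delta_cost, 0, tolerance = 1e-9)
  expect_equal(inc$delta_qaly, 0, tolerance = 1e-9)
})

test_that("expected event counts accumulate incident fractions", {
  p <- make_fixture("no_events")
  counts <- expected_event_counts(run_cohort("riva", p))
  expect_true(all(counts == 0))

  tr <- run_cohort("vka", base_params())
  counts <- expected_event_counts(tr)
  expect_equal(unname(counts[["strokes"]]),
               unname(counts[["major_is"]] + counts[["minor_is"]]))
  expect_equal(unname(counts[["bleeds"]]),
               unname(counts[["ic"]] + counts[["minor_ec"]] + counts[["major_ec"]]))
  expect_true(all(counts >= 0))
})

test_that("incremental classification follows the dominance rules", {
  mk <- function(cost, qaly, ly = qaly / 0.76) {
    structure(list(cost_total = cost, qaly_discounted = qaly,
                   ly_discounted = ly), class = "afcea_result")
  }
  dom <- incremental_analysis(mk(7761, 6.72), mk(8000, 6.50))
  expect_identical(dom$classification, "dominant")
  expect_true(is.na(dom$icer_qaly))

  icer <- incremental_analysis(mk(8500, 6.55), mk(8000, 6.50))
  expect_identical(icer$classification, "icer")
  expect_equal(icer$icer_qaly, 500 / 0.05, tolerance = 1e-9)

  same <- incremental_analysis(mk(8000, 6.50), mk(8000, 6.50))
  expect_equal(same$delta_cost, 0)
  expect_equal(same$icer_qaly, 0)

  flagged <- incremental_analysis(mk(8100, 6.50), mk(8000, 6.50))
  expect_identical(flagged$classification, "dominated")
  expect_true(is.na(flagged$icer_qaly))
})

test_that("results table carries one labelled row per strategy", {
  res <- run_comparison(base_params())
  df <- results_as_data_frame(res)
  expect_identical(df$strategy, c("riva", "vka"))
  expect_identical(ncol(df), 11L)
  expect_equal(df$cost_total[1], res$riva$cost_total)
})
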