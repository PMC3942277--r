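test_that("lognormal parameters recover the published confidence interval", {
  lp <- lognormal_from_ci(0.79, 0.65, 0.95)
  expect_equal(lp$location, log(0.79), tolerance = 1e-9)
  expect_equal(lp$location, -0.23572, tolerance = 1e-4)
  expect_equal(lp$scale, (log(0.95) - log(0.65)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(lp$scale, 0.09681, tolerance = 1e-4)

  expect_identical(lognormal_from_ci(0.8, 0.8, 0.8)$scale, 0)
  expect_error(lognormal_from_ci(0.8, -1, 0.9), "positive")
  expect_error(lognormal_from_ci(0.5, 0.6, 0.9), "lo <= point <= hi")

  set.seed(101)
  draws <- rlnorm(1e5, lp$location, lp$scale)
  q <- quantile(draws, c(0.025, 0.975))
  expect_equal(unname(q[1]), 0.65, tolerance = 0.02)
  expect_equal(unname(q[2]), 0.95, tolerance = 0.02)
})

test_that("moment matching reproduces the target mean and sd", {
  b <- moment_match("beta", 0.5, 0.1)
  expect_equal(b$shape1, 12, tolerance = 1e-9)
  expect_equal(b$shape2, 12, tolerance = 1e-9)
  g <- moment_match("gamma", 100, 20)
  expect_equal(g$shape, 25, tolerance = 1e-9)
  expect_equal(g$scale, 4, tolerance = 1e-9)
  expect_error(moment_match("beta", 0.5, 0.5), "infeasible")

  # analytic recovery for a spread of parameters
  for (m in c(0.05, 0.3, 0.779)) {
    for (se in c(0.2 * m, 0.05)) {
      p <- moment_match("beta", m, se)
      mu <- p$shape1 / (p$shape1 + p$shape2)
      v <- p$shape1 * p$shape2 /
        ((p$shape1 + p$shape2)^2 * (p$shape1 + p$shape2 + 1))
      expect_equal(mu, m, tolerance = 1e-9)
      expect_equal(sqrt(v), se, tolerance = 1e-9)
    }
  }
  # empirical recovery within 3 standard errors at 1e5 draws
  set.seed(7)
  p <- moment_match("gamma", 1093, 0.2 * 1093)
  x <- rgamma(1e5, shape = p$shape, scale = p$scale)
  expect_lt(abs(mean(x) - 1093), 3 * sd(x) / sqrt(1e5))
})

test_that("CEAC is the net-monetary-benefit exceedance curve", {
  samples <- data.frame(delta_cost = c(-100, 50, 200, -10),
                        delta_qaly = c(0.1, 0.001, 0.02, -0.01))
  # brute-force NMB at 30,000: 3100, -20, 400, -290 -> half qualify
  expect_equal(ceac(samples, 30000)$probability, 0.5)
  # at zero willingness to pay only cost savings count
  expect_equal(ceac(samples, 0)$probability, mean(samples$delta_cost <= 0))
  dominant <- data.frame(delta_cost = -(1:4), delta_qaly = (1:4) / 100)
  cc <- ceac(dominant, c(0, 30000, 1e6))
  expect_true(all(cc$probability == 1))
  # proper curve: probabilities in [0, 1]; limit is the positive-gain fraction
  cc2 <- ceac(samples, c(0, 1e4, 1e9))
  expect_true(all(cc2$probability >= 0 & cc2$probability <= 1))
  expect_equal(cc2$probability[3], mean(samples$delta_qaly >= 0))
  expect_error(ceac(samples[0, ], 30000), "samples")
  expect_error(ceac(samples, numeric()), "grid")
})

test_that("PSA is seed-deterministic and degenerates to the base case with no specs", {
  p <- base_params()
  fixed <- run_psa(p, specs = list(), n_iterations = 2, seed = 1)
  base <- run_comparison(p)
  expect_equal(fixed$delta_cost,
               rep(base$incremental$delta_cost, 2), tolerance = 1e-12)
  expect_equal(fixed$delta_qaly,
               rep(base$incremental$delta_qaly, 2), tolerance = 1e-12)

  a <- run_psa(p, n_iterations = 3, seed = 42)
  b <- run_psa(p, n_iterations = 3, seed = 42)
  expect_identical(a, b)
  c <- run_psa(p, n_iterations = 3, seed = 43)
  expect_false(identical(a$delta_cost, c$delta_cost))
  expect_true(all(is.finite(a$delta_cost)) && all(is.finite(a$delta_qaly)))
})

test_that("the default distribution set covers risks, effects, utilities and costs", {
  p <- base_params()
  specs <- default_psa_specs(p)
  fams <- vapply(specs, `[[`, "", "family")
  paths <- vapply(specs, `[[`, "", "path")
  expect_identical(sum(fams == "lognormal"), 6L)
  expect_true(any(startsWith(paths, "event_rates_vka") & fams == "beta"))
  expect_true(any(startsWith(paths, "costs.acute") & fams == "gamma"))
  expect_true(any(startsWith(paths, "utilities") & fams == "beta"))
  expect_identical(sum(fams == "beta_complement"), 1L)
  # structural zeros stay fixed
  expect_false("mortality.case_fatality.se" %in% paths)
})

test_that("one-way sensitivity at the base value reproduces the base case", {
  p <- base_params()
  plan <- data.frame(parameter = "costs.visit.vka_subsequent", low = 22,
                     high = 22)
  tor <- one_way_sensitivity(p, plan)
  base <- run_comparison(p)$incremental
  expect_identical(tor$class_low, base$classification)
  expect_identical(tor$class_high, base$classification)
  expect_error(
    one_way_sensitivity(p, data.frame(parameter = "no.such.path", low = 0,
                                      high = 1)),
    "unknown parameter path")
  expect_error(
    one_way_sensitivity(p, data.frame(parameter = "costs.visit.other",
                                      low = 50, high = 60)),
    "low <= base <= high")
})

test_that("VKA maintenance visit frequency drives the decision as tabulated", {
  p <- base_params()
  plan <- data.frame(parameter = "costs.visits_per_cycle.vka_maintenance",
                     low = 1, high = 5)
  tor <- one_way_sensitivity(p, plan)
  expect_identical(tor$class_low, "icer")
  expect_gt(tor$icer_low, 0)
  expect_identical(tor$class_high, "dominant")
})

test_that("transport uptake flips the decision between its extremes", {
  p <- base_params()
  plan <- data.frame(parameter = "costs.transport.uptake", low = 0, high = 1)
  tor <- one_way_sensitivity(p, plan)
  expect_identical(tor$class_low, "icer")
  expect_identical(tor$class_high, "dominant")
})

test_that("scenario definitions apply the intended parameter swaps", {
  p <- base_params()
  itt <- scenario_parameters("itt_aspirin", p)
  expect_identical(itt$effect$population, "ITT")
  expect_identical(itt$effect$rr_is$point, 0.99)
  expect_identical(itt$effect$rr_ic$point, p$effect$rr_ic$point)

  none <- scenario_parameters("sot_none", p)
  expect_identical(none$persistence$second_line, "none")
  expect_gt(none$event_rates_secondline$ischemic_stroke,
            p$event_rates_secondline$ischemic_stroke)

  nod <- scenario_parameters("no_vka_disutility", p)
  expect_identical(nod$utilities$vka_multiplier, 1)

  r9 <- scenario_parameters("rebate_9", p)
  expect_equal(effective_daily_drug_cost(r9$costs)[["riva"]], 2.16 * 0.91)
  r14 <- scenario_parameters("rebate_14", p)
  expect_equal(effective_daily_drug_cost(r14$costs)[["riva"]],
               2.16 * 0.91 * 0.95)
  expect_error(scenario_parameters("bogus", p), "unknown scenario")
})
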