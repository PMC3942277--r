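test_that("state space enumerates both lines for every alive state, deterministically", {
  ss <- build_state_space()
  expect_length(ss, 26)
  expect_identical(ss, build_state_space())
  expect_identical(sum(endsWith(ss, "|first")), 12L)
  expect_identical(sum(endsWith(ss, "|second")), 12L)
  expect_true(all(c("dead_event", "dead_other") %in% ss))
})

test_that("transition vectors are proper distributions from every compartment", {
  p <- base_params()
  ss <- build_state_space()
  for (first in c(TRUE, FALSE)) {
    for (comp in ss) {
      state <- sub("\\|.*$", "", comp)
      line <- if (grepl("\\|", comp)) sub("^.*\\|", "", comp) else "first"
      for (age in c(75, 88, 104)) {
        v <- transition_probabilities(state, line, age, p, "riva",
                                      first_cycle = first)
        expect_equal(sum(v), 1, tolerance = 1e-12)
        expect_true(all(v >= 0))
      }
    }
  }
})

test_that("acute intracranial bleed resolves by case fatality and switches survivors off OAC", {
  p <- unclass(base_params())
  p$mortality$life_table <- flat_life_table(0)
  p <- validate_parameters(p)
  v <- transition_probabilities("acute_ic", "first", 75, p, "vka")
  expect_equal(v[["dead_event"]], 0.388)
  expect_equal(v[["post_ic|second"]], 0.612)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  # on the second line there is no further switching
  v2 <- transition_probabilities("acute_ic", "second", 75, p, "vka")
  expect_equal(v2[["post_ic|second"]], 0.612)
})

test_that("with no risks at all the cohort stays in stable AF", {
  p <- unclass(make_fixture("no_events"))
  p$mortality$life_table <- flat_life_table(0)
  p$persistence$disc_first_cycle <- list(riva = 0, vka = 0)
  p$persistence$disc_subsequent <- list(riva = 0, vka = 0)
  p <- validate_parameters(p)
  v <- transition_probabilities("stable_af", "first", 80, p, "riva")
  expect_equal(v[["stable_af|first"]], 1)
  tr <- run_cohort("riva", p)
  expect_equal(unname(tr$occupancy[10, "stable_af|first"]), 1)
})

test_that("stable-state exit mass equals the sum of the per-cycle event rates", {
  p <- unclass(base_params())
  p$mortality$life_table <- flat_life_table(0)
  p$persistence$disc_first_cycle <- list(riva = 0, vka = 0)
  p$persistence$disc_subsequent <- list(riva = 0, vka = 0)
  p <- validate_parameters(p)
  v <- transition_probabilities("stable_af", "first", 75, p, "vka")
  exit <- 1 - v[["stable_af|first"]]
  expect_equal(exit, sum(table1_vka_rates), tolerance = 1e-12)
})

test_that("every cycle of every trace conserves mass and dead mass never decreases", {
  for (strategy in c("riva", "vka")) {
    tr <- run_cohort(strategy, base_params())
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    dead <- tr$occupancy[, "dead_event"] + tr$occupancy[, "dead_other"]
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-15))
  }
})

test_that("pure background mortality reproduces geometric survival and its discounted closed form", {
  qc <- 0.01                               # per-cycle death probability
  annual <- 1 - (1 - qc)^4
  p <- survival_toy_params(annual, terminal_age = 100, discount = 0.035)
  tr <- run_cohort("riva", p)
  alive <- 1 - tr$occupancy[, "dead_event"] - tr$occupancy[, "dead_other"]
  t_idx <- seq_len(60)
  expect_equal(unname(alive[t_idx]), (1 - qc)^(t_idx - 1), tolerance = 1e-10)

  # closed form: fast-decaying toy whose mass is exhausted before the
  # terminal age, so every cycle is exactly geometric
  qc2 <- 0.1
  p2 <- survival_toy_params(1 - (1 - qc2)^4, terminal_age = 110,
                            discount = 0.035)
  tr2 <- run_cohort("riva", p2)
  res <- accumulate_outcomes(tr2, p2)
  d <- 1.035^(-1 / 4)
  n <- nrow(tr2$occupancy)
  closed <- 0.25 * sum(((1 - qc2) * d)^(seq_len(n) - 1))
  expect_equal(res$ly_discounted, closed, tolerance = 1e-6)
})

test_that("first events deplete the never-event state at the closed-form rate", {
  p_is <- 0.05
  p <- is_only_params(p_is, terminal_age = 85)
  tr <- run_cohort("vka", p)
  t_idx <- c(5, 10, 20, 30)
  expect_equal(unname(tr$occupancy[t_idx, "stable_af|first"]),
               (1 - p_is)^(t_idx - 1), tolerance = 1e-10)
})

test_that("discount factors follow the quarterly compounding convention", {
  expect_identical(discount_factor(0, 0.035), 1)
  expect_identical(discount_factor(7, 0), 1)
  expect_equal(discount_factor(4, 0.035), 1 / 1.035, tolerance = 1e-9)
  expect_error(discount_factor(-1, 0.035), ">= 0")
})

test_that("trace exports one labelled row per cycle", {
  tr <- run_cohort("riva", base_params())
  df <- trace_as_data_frame(tr)
  expect_identical(nrow(df), nrow(tr$occupancy))
  expect_true(all(c("cycle", "age", "discount", "stable_af.first",
                    "dead_other") %in% names(df)))
  expect_equal(df$age[1], 75)
})
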