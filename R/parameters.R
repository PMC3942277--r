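# Model inputs: event rates, treatment effects, mortality, utilities, costs,
# persistence and run settings, plus the time-scale and payer pricing rules.

EVENT_KEYS <- c("ischemic_stroke", "myocardial_infarction", "systemic_embolism",
                "intracranial_bleed", "minor_extracranial_bleed",
                "major_extracranial_bleed")

RR_KEYS <- c("rr_is", "rr_mi", "rr_se", "rr_ic", "rr_major_ec", "rr_minor_ec")

afcea_stop <- function(path, msg) {
  stop(sprintf("parameter validation error at '%s': %s", path, msg),
       call. = FALSE)
}

chk_number <- function(x, path) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    afcea_stop(path, "must be a single finite number")
  invisible(x)
}

chk_prob <- function(x, path) {
  chk_number(x, path)
  if (x < 0 || x > 1) afcea_stop(path, sprintf("probability %g outside [0, 1]", x))
  invisible(x)
}

chk_nonneg <- function(x, path) {
  chk_number(x, path)
  if (x < 0) afcea_stop(path, sprintf("value %g must be non-negative", x))
  invisible(x)
}

chk_fields <- function(block, required, path) {
  if (!is.list(block)) afcea_stop(path, "must be a mapping/list")
  missing <- setdiff(required, names(block))
  if (length(missing))
    afcea_stop(path, paste("missing field(s):", paste(missing, collapse = ", ")))
  unknown <- setdiff(names(block), required)
  if (length(unknown))
    afcea_stop(path, paste("unknown field(s):", paste(unknown, collapse = ", ")))
  invisible(block)
}

#' Convert an annual probability to a 3-month cycle probability
#'
#' Uses the constant-hazard relation `1 - (1 - annual)^(1/4)`, the standard
#' quarterly-rate conversion for state-transition models with 3-month cycles.
#'
#' @param annual Annual event probability, in `[0, 1]`. Vectorised.
#' @return Per-cycle (3-month) probability.
#' @seealso [cycle_to_annual_prob()] for the inverse.
#' @export
#' @examples
#' annual_to_cycle_prob(0.04)
annual_to_cycle_prob <- function(annual) {
  if (!is.numeric(annual) || any(!is.finite(annual)))
    afcea_stop("annual", "must be finite numeric")
  if (any(annual < 0 | annual > 1))
    afcea_stop("annual", "probability outside [0, 1]")
  1 - (1 - annual)^(1 / 4)
}

#' @rdname annual_to_cycle_prob
#' @param cycle Per-cycle (3-month) probability, in `[0, 1]`.
#' @export
cycle_to_annual_prob <- function(cycle) {
  if (!is.numeric(cycle) || any(!is.finite(cycle)))
    afcea_stop("cycle", "must be finite numeric")
  if (any(cycle < 0 | cycle > 1))
    afcea_stop("cycle", "probability outside [0, 1]")
  1 - (1 - cycle)^4
}

#' Per-cycle discontinuation probabilities from persistence proportions
#'
#' Converts the proportion of patients persisting on therapy at 3 months (`x`)
#' and at 12 months (`y`) into a first-cycle discontinuation probability
#' `1 - x` and a constant per-cycle probability `1 - (y/x)^(1/3)` for the
#' three cycles between month 3 and month 12.
#'
#' @param persist_3mo Proportion persisting at 3 months, in `(0, 1]`.
#' @param persist_12mo Proportion persisting at 12 months; must not exceed
#'   `persist_3mo`.
#' @return A list with elements `first_cycle` and `subsequent`.
#' @export
#' @examples
#' discontinuation_from_persistence(0.911, 0.7962)
discontinuation_from_persistence <- function(persist_3mo, persist_12mo) {
  chk_prob(persist_3mo, "persist_3mo")
  chk_prob(persist_12mo, "persist_12mo")
  if (persist_3mo <= 0) afcea_stop("persist_3mo", "must be positive")
  if (persist_12mo > persist_3mo)
    afcea_stop("persist_12mo",
               "persistence at 12 months exceeds persistence at 3 months")
  list(first_cycle = 1 - persist_3mo,
       subsequent  = 1 - (persist_12mo / persist_3mo)^(1 / 3))
}

#' Apply a relative risk to a per-cycle event probability
#'
#' The treatment effect is applied multiplicatively on the per-cycle
#' probability and clamped at 1. At the event probabilities used here
#' (at most a few percent per cycle) the difference from a rate-space
#' application is negligible; the clamp only engages for extreme inputs.
#'
#' @param baseline Per-cycle event probability under the comparator.
#' @param rr Relative risk (> 0) of treatment versus comparator. Vectorised.
#' @return Per-cycle probability under treatment, `min(1, baseline * rr)`.
#' @export
treated_event_probability <- function(baseline, rr) {
  if (!is.numeric(baseline) || any(!is.finite(baseline)) || any(baseline < 0) ||
      any(baseline > 1))
    afcea_stop("baseline", "probability outside [0, 1]")
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0))
    afcea_stop("rr", "relative risk must be positive and finite")
  pmin(1, baseline * rr)
}

#' Payer cost per day of drug under Greek reference pricing and rebates
#'
#' Implements the positive-list reimbursement rule: when the retail price
#' exceeds the reference price the payer covers the reference price minus the
#' patient co-payment plus half of the retail-reference difference; when the
#' retail price does not exceed the reference price the payer covers the
#' reference price minus the co-payment; with no reference price (drugs not
#' yet on the positive list) the retail price applies in full. Entry and
#' volume rebates then reduce the payer cost multiplicatively.
#'
#' @param retail Retail price per day (€).
#' @param reference Reference (reimbursement) price per day (€), or `NA` when
#'   the drug has no social-security reference price.
#' @param copay_rate Patient co-payment fraction (default 0.25).
#' @param rebate_entry Manufacturer rebate to enter the positive list
#'   (fraction, default 0).
#' @param rebate_volume Additional volume-based rebate (fraction, default 0).
#' @return Payer cost per day (€).
#' @export
payer_drug_cost_per_day <- function(retail, reference = NA_real_,
                                    copay_rate = 0.25,
                                    rebate_entry = 0, rebate_volume = 0) {
  chk_nonneg(retail, "retail")
  chk_prob(copay_rate, "copay_rate")
  chk_prob(rebate_entry, "rebate_entry")
  chk_prob(rebate_volume, "rebate_volume")
  base <- if (is.na(reference)) {
    retail
  } else {
    chk_nonneg(reference, "reference")
    if (retail > reference) {
      reference * (1 - copay_rate) + 0.5 * (retail - reference)
    } else {
      reference * (1 - copay_rate)
    }
  }
  base * (1 - rebate_entry) * (1 - rebate_volume)
}

#' Monitoring and transport cost for one model cycle
#'
#' VKA therapy requires INR-guided dose titration: weekly visits during the
#' first month of therapy (the first at the higher first-visit tariff) and
#' monthly visits thereafter, so the initiation cycle holds 6 visits and each
#' maintenance cycle `visits_per_cycle$vka_maintenance` (default 3). Fixed-dose
#' therapy (rivaroxaban) needs no INR monitoring, only routine visits
#' (`visits_per_cycle$other` per cycle). Payer-sponsored patient transport is
#' attached to VKA monitoring visits only, for the `transport$uptake` fraction
#' of patients. Visit tariffs are INR-test-inclusive; an additive INR test
#' cost can be configured via `costs$inr_test` (default 0).
#'
#' @param line One of `"vka"`, `"riva"`, `"secondline"`.
#' @param phase One of `"initiation"` (first cycle on the line) or
#'   `"maintenance"`.
#' @param costs The `costs` block of a parameter set.
#' @return Named numeric vector `c(monitoring =, transport =)` in € per cycle
#'   per patient on the line.
#' @export
monitoring_cost_per_cycle <- function(line = c("vka", "riva", "secondline"),
                                      phase = c("maintenance", "initiation"),
                                      costs) {
  line <- match.arg(line)
  phase <- match.arg(phase)
  v <- costs$visit
  vpc <- costs$visits_per_cycle
  inr <- if (is.null(costs$inr_test)) 0 else costs$inr_test
  if (line == "vka") {
    if (phase == "initiation") {
      # 4 weekly visits in month 1 (first at the first-visit tariff) plus 2
      # monthly visits for the remainder of the quarter
      n_visits <- 6
      monitoring <- v$vka_first + 5 * v$vka_subsequent + n_visits * inr
    } else {
      n_visits <- vpc$vka_maintenance
      monitoring <- n_visits * (v$vka_subsequent + inr)
    }
    transport <- n_visits * costs$transport$uptake * costs$transport$cost_per_visit
  } else {
    n_visits <- if (line == "riva") vpc$other else vpc$secondline
    monitoring <- n_visits * v$other
    transport <- 0
  }
  c(monitoring = monitoring, transport = transport)
}

#' Effective daily drug acquisition costs for the three treatment lines
#'
#' Applies [payer_drug_cost_per_day()] to the configured daily prices with the
#' configured rebates. The base case carries zero rebates; rebate scenarios
#' set `costs$rebate$entry` / `costs$rebate$volume`.
#'
#' @param costs The `costs` block of a parameter set.
#' @return Named vector with elements `riva`, `vka`, `secondline` (€/day).
#' @export
effective_daily_drug_cost <- function(costs) {
  reb <- costs$rebate
  f <- function(x) payer_drug_cost_per_day(
    x, reference = NA_real_, copay_rate = costs$copay_rate,
    rebate_entry = reb$entry, rebate_volume = reb$volume)
  c(riva = f(costs$drug_daily$riva),
    vka = f(costs$drug_daily$vka),
    secondline = f(costs$drug_daily$secondline))
}

validate_event_rates <- function(block, path) {
  chk_fields(block, EVENT_KEYS, path)
  for (k in EVENT_KEYS) chk_prob(block[[k]], paste0(path, ".", k))
  invisible(block)
}

validate_rr <- function(block, path) {
  chk_fields(block, c("point", "lower", "upper"), path)
  for (k in c("point", "lower", "upper")) {
    chk_number(block[[k]], paste0(path, ".", k))
    if (block[[k]] <= 0) afcea_stop(paste0(path, ".", k), "relative risk must be > 0")
  }
  if (!(block$lower <= block$point && block$point <= block$upper))
    afcea_stop(path, "requires lower <= point <= upper")
  invisible(block)
}

validate_life_table <- function(lt, path, start_age) {
  chk_fields(lt, c("ages", "qx"), path)
  if (length(lt$ages) != length(lt$qx))
    afcea_stop(path, "ages and qx differ in length")
  if (any(diff(lt$ages) != 1))
    afcea_stop(paste0(path, ".ages"), "must be consecutive integer ages")
  for (i in seq_along(lt$qx)) chk_prob(lt$qx[[i]], sprintf("%s.qx[%d]", path, i))
  if (lt$ages[1] > start_age)
    afcea_stop(path, sprintf("life table starts after start_age %d", start_age))
  if (utils::tail(lt$qx, 1) != 1)
    afcea_stop(path, "terminal-age annual death probability must be 1")
  invisible(lt)
}

#' Validate a full parameter set
#'
#' Checks structural completeness (every block and field present, nothing
#' unknown) and all range invariants: probabilities in `[0, 1]`, positive
#' relative risks with ordered confidence bounds, non-negative costs, a life
#' table covering the starting age through a terminal age with annual death
#' probability 1, and severity cost weights summing to 1.
#'
#' @param params A nested parameter list, typically from [load_config()] or
#'   [make_fixture()].
#' @return The validated parameter set, invisibly, with class
#'   `afcea_parameters`.
#' @export
validate_parameters <- function(params) {
  chk_fields(params, c("event_rates_vka", "event_rates_secondline", "effect",
                       "mortality", "utilities", "costs", "persistence",
                       "settings"), "parameters")

  validate_event_rates(params$event_rates_vka, "event_rates_vka")
  validate_event_rates(params$event_rates_secondline, "event_rates_secondline")

  eff <- params$effect
  chk_fields(eff, c("population", RR_KEYS, "itt"), "effect")
  if (!eff$population %in% c("SOT", "ITT"))
    afcea_stop("effect.population", "must be 'SOT' or 'ITT'")
  for (k in RR_KEYS) validate_rr(eff[[k]], paste0("effect.", k))
  chk_fields(eff$itt, c("rr_is", "rr_mi", "rr_se"), "effect.itt")
  for (k in names(eff$itt)) validate_rr(eff$itt[[k]], paste0("effect.itt.", k))

  mort <- params$mortality
  chk_fields(mort, c("case_fatality", "post_excess", "start_age", "life_table"),
             "mortality")
  chk_fields(mort$case_fatality,
             c("major_is", "minor_is", "major_ec", "minor_ec", "ic", "se", "mi"),
             "mortality.case_fatality")
  for (k in names(mort$case_fatality))
    chk_prob(mort$case_fatality[[k]], paste0("mortality.case_fatality.", k))
  chk_fields(mort$post_excess, c("major_is", "minor_is", "ic", "mi"),
             "mortality.post_excess")
  for (k in names(mort$post_excess))
    chk_prob(mort$post_excess[[k]], paste0("mortality.post_excess.", k))
  chk_number(mort$start_age, "mortality.start_age")
  validate_life_table(mort$life_table, "mortality.life_table", mort$start_age)

  u <- params$utilities
  chk_fields(u, c("baseline", "vka_multiplier", "acute", "post"), "utilities")
  chk_prob(u$baseline, "utilities.baseline")
  chk_prob(u$vka_multiplier, "utilities.vka_multiplier")
  chk_fields(u$acute, c("major_is", "minor_is", "mi", "minor_ec", "major_ec",
                        "ic", "se"), "utilities.acute")
  for (k in names(u$acute)) chk_prob(u$acute[[k]], paste0("utilities.acute.", k))
  chk_fields(u$post, c("minor_is", "major_is", "mi", "ic"), "utilities.post")
  for (k in names(u$post)) chk_prob(u$post[[k]], paste0("utilities.post.", k))

  co <- params$costs
  chk_fields(co, c("drug_daily", "visit", "acute", "followup", "transport",
                   "rebate", "copay_rate", "inr_test", "visits_per_cycle"),
             "costs")
  chk_fields(co$drug_daily, c("riva", "vka", "secondline"), "costs.drug_daily")
  for (k in names(co$drug_daily))
    chk_nonneg(co$drug_daily[[k]], paste0("costs.drug_daily.", k))
  chk_fields(co$visit, c("vka_first", "vka_subsequent", "other"), "costs.visit")
  for (k in names(co$visit)) chk_nonneg(co$visit[[k]], paste0("costs.visit.", k))
  chk_fields(co$acute, c("minor_is", "moderate_is", "severe_is", "se", "ic",
                         "minor_ec", "major_ec", "mi"), "costs.acute")
  for (k in names(co$acute)) chk_nonneg(co$acute[[k]], paste0("costs.acute.", k))
  chk_fields(co$followup, c("major_is", "ic", "mi"), "costs.followup")
  for (k in names(co$followup))
    chk_nonneg(co$followup[[k]], paste0("costs.followup.", k))
  chk_fields(co$transport, c("cost_per_visit", "uptake"), "costs.transport")
  chk_nonneg(co$transport$cost_per_visit, "costs.transport.cost_per_visit")
  chk_prob(co$transport$uptake, "costs.transport.uptake")
  chk_fields(co$rebate, c("entry", "volume"), "costs.rebate")
  chk_prob(co$rebate$entry, "costs.rebate.entry")
  chk_prob(co$rebate$volume, "costs.rebate.volume")
  chk_prob(co$copay_rate, "costs.copay_rate")
  chk_nonneg(co$inr_test, "costs.inr_test")
  chk_fields(co$visits_per_cycle, c("vka_maintenance", "other", "secondline"),
             "costs.visits_per_cycle")
  for (k in names(co$visits_per_cycle))
    chk_nonneg(co$visits_per_cycle[[k]], paste0("costs.visits_per_cycle.", k))

  pe <- params$persistence
  chk_fields(pe, c("disc_first_cycle", "disc_subsequent", "disc_horizon_cycles",
                   "second_line", "ic_bleed_discontinuation_prob"),
             "persistence")
  chk_fields(pe$disc_first_cycle, c("riva", "vka"), "persistence.disc_first_cycle")
  chk_fields(pe$disc_subsequent, c("riva", "vka"), "persistence.disc_subsequent")
  for (k in c("riva", "vka")) {
    chk_prob(pe$disc_first_cycle[[k]], paste0("persistence.disc_first_cycle.", k))
    chk_prob(pe$disc_subsequent[[k]], paste0("persistence.disc_subsequent.", k))
  }
  chk_number(pe$disc_horizon_cycles, "persistence.disc_horizon_cycles")
  if (pe$disc_horizon_cycles < 1)
    afcea_stop("persistence.disc_horizon_cycles", "must be >= 1")
  if (!pe$second_line %in% c("aspirin", "none"))
    afcea_stop("persistence.second_line", "must be 'aspirin' or 'none'")
  chk_prob(pe$ic_bleed_discontinuation_prob,
           "persistence.ic_bleed_discontinuation_prob")

  se <- params$settings
  chk_fields(se, c("cycle_length_days", "discount_rate_annual", "terminal_age",
                   "wtp_grid", "stroke_major_fraction",
                   "stroke_major_cost_weights", "half_cycle_correction"),
             "settings")
  chk_nonneg(se$cycle_length_days, "settings.cycle_length_days")
  chk_nonneg(se$discount_rate_annual, "settings.discount_rate_annual")
  chk_number(se$terminal_age, "settings.terminal_age")
  if (se$terminal_age <= params$mortality$start_age)
    afcea_stop("settings.terminal_age", "must exceed mortality.start_age")
  for (i in seq_along(se$wtp_grid))
    chk_nonneg(se$wtp_grid[[i]], sprintf("settings.wtp_grid[%d]", i))
  chk_prob(se$stroke_major_fraction, "settings.stroke_major_fraction")
  w <- se$stroke_major_cost_weights
  chk_fields(w, c("moderate", "severe"), "settings.stroke_major_cost_weights")
  chk_prob(w$moderate, "settings.stroke_major_cost_weights.moderate")
  chk_prob(w$severe, "settings.stroke_major_cost_weights.severe")
  if (abs(w$moderate + w$severe - 1) > 1e-9)
    afcea_stop("settings.stroke_major_cost_weights", "weights must sum to 1")
  if (!is.logical(se$half_cycle_correction) || length(se$half_cycle_correction) != 1L)
    afcea_stop("settings.half_cycle_correction", "must be TRUE or FALSE")

  class(params) <- c("afcea_parameters", "list")
  invisible(params)
}

#' @export
print.afcea_parameters <- function(x, ...) {
  cat("<afcea_parameters>\n")
  cat(sprintf("  start age %g, terminal age %g, %s effects, second line: %s\n",
              x$mortality$start_age, x$settings$terminal_age,
              x$effect$population, x$persistence$second_line))
  cat(sprintf("  discount %.1f%%/yr, cycle %.4g days, VKA utility multiplier %.3g\n",
              100 * x$settings$discount_rate_annual,
              x$settings$cycle_length_days, x$utilities$vka_multiplier))
  invisible(x)
}
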