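# Aggregation of a cohort trace into discounted QALYs, life-years,
# decomposed costs and event counts, and the incremental comparison.

state_of <- function(comp) sub("\\|.*$", "", comp)
line_of <- function(comp) sub("^.*\\|", "", comp)

# per-compartment utility for a strategy; the VKA treatment disutility
# multiplier applies to all alive states while on first-line VKA
compartment_utilities <- function(params, strategy) {
  comp <- build_state_space()
  u <- params$utilities
  base <- vapply(comp, function(cm) {
    s <- state_of(cm)
    if (s %in% DEAD_STATES) return(0)
    if (s == "stable_af") return(u$baseline)
    if (startsWith(s, "acute_")) return(u$acute[[sub("acute_", "", s)]])
    u$post[[sub("post_", "", s)]]
  }, numeric(1))
  if (strategy == "vka") {
    on_vka <- !state_of(comp) %in% DEAD_STATES & line_of(comp) == "first"
    base[on_vka] <- base[on_vka] * u$vka_multiplier
  }
  base
}

acute_event_costs <- function(params) {
  ca <- params$costs$acute
  w <- params$settings$stroke_major_cost_weights
  c(major_is = w$moderate * ca$moderate_is + w$severe * ca$severe_is,
    minor_is = ca$minor_is, se = ca$se, mi = ca$mi,
    minor_ec = ca$minor_ec, major_ec = ca$major_ec, ic = ca$ic)
}

#' Aggregate a cohort trace into lifetime outcomes for one strategy
#'
#' Per cycle, the QALY contribution is occupancy times state utility (with the
#' VKA disutility multiplier on first-line VKA time) times cycle length in
#' years times the discount factor. Drug cost accrues per day on each line;
#' monitoring and payer transport follow [monitoring_cost_per_cycle()], with
#' the VKA initiation schedule in the first model cycle; acute event costs
#' attach to incident events (major stroke priced as the configured
#' moderate/severe mix); follow-up costs attach to chronic post-major-stroke,
#' post-intracranial-bleed and post-myocardial-infarction occupancy each
#' cycle. An optional half-cycle correction averages adjacent-cycle occupancy
#' for the continuous accruals.
#'
#' @param trace An `afcea_trace` from [run_cohort()].
#' @param params The parameter set the trace was generated from.
#' @return An object of class `afcea_result`: list with discounted and
#'   undiscounted QALYs and life-years, total and decomposed discounted costs
#'   (`cost_acquisition`, `cost_monitoring` including transport,
#'   `cost_events` acute plus follow-up) and expected lifetime event counts.
#' @export
accumulate_outcomes <- function(trace, params) {
  stopifnot(inherits(trace, "afcea_trace"))
  strategy <- trace$strategy
  comp <- build_state_space()
  occ <- trace$occupancy
  if (!identical(colnames(occ), comp))
    stop("trace/parameter shape mismatch", call. = FALSE)
  n <- nrow(occ)
  d <- trace$discount
  cyc_years <- params$settings$cycle_length_days / 365.25
  cyc_days <- params$settings$cycle_length_days

  if (isTRUE(params$settings$half_cycle_correction) && n > 1) {
    occ_c <- (occ + rbind(occ[-1, , drop = FALSE], occ[n, , drop = FALSE])) / 2
  } else {
    occ_c <- occ
  }

  first_mask <- line_of(comp) == "first" & !comp %in% DEAD_STATES
  second_mask <- line_of(comp) == "second"
  alive_mask <- !comp %in% DEAD_STATES
  on_first <- occ_c[, first_mask, drop = FALSE] |> rowSums()
  on_second <- occ_c[, second_mask, drop = FALSE] |> rowSums()
  alive <- occ_c[, alive_mask, drop = FALSE] |> rowSums()

  u <- compartment_utilities(params, strategy)
  qaly_cycle <- as.vector(occ_c %*% u) * cyc_years
  ly_cycle <- alive * cyc_years

  daily <- effective_daily_drug_cost(params$costs)
  first_daily <- daily[[strategy]]
  drug_cycle <- (on_first * first_daily + on_second * daily[["secondline"]]) * cyc_days

  first_line_id <- if (strategy == "vka") "vka" else "riva"
  mon_init <- monitoring_cost_per_cycle(first_line_id, "initiation", params$costs)
  mon_maint <- monitoring_cost_per_cycle(first_line_id, "maintenance", params$costs)
  mon_second <- monitoring_cost_per_cycle("secondline", "maintenance", params$costs)
  mon_first_per <- c(sum(mon_init), rep(sum(mon_maint), n - 1))[seq_len(n)]
  mon_cycle <- on_first * mon_first_per + on_second * sum(mon_second)

  ev_cost <- acute_event_costs(params)
  acute_cycle <- as.vector(trace$incidence %*% ev_cost)
  fu <- params$costs$followup
  post_occ <- function(s) occ_c[, paste(s, "first", sep = "|")] +
    occ_c[, paste(s, "second", sep = "|")]
  followup_cycle <- post_occ("post_major_is") * fu$major_is +
    post_occ("post_ic") * fu$ic + post_occ("post_mi") * fu$mi

  counts <- expected_event_counts(trace)

  res <- list(
    strategy = strategy,
    qaly_discounted = sum(qaly_cycle * d),
    qaly_undiscounted = sum(qaly_cycle),
    ly_discounted = sum(ly_cycle * d),
    ly_undiscounted = sum(ly_cycle),
    cost_acquisition = sum(drug_cycle * d),
    cost_monitoring = sum(mon_cycle * d),
    cost_events = sum((acute_cycle + followup_cycle) * d),
    expected_strokes = counts[["strokes"]],
    expected_bleeds = counts[["bleeds"]],
    event_counts = counts
  )
  res$cost_total <- res$cost_acquisition + res$cost_monitoring + res$cost_events
  structure(res, class = "afcea_result")
}

#' @export
print.afcea_result <- function(x, ...) {
  cat(sprintf("<afcea_result> %s\n", x$strategy))
  cat(sprintf("  QALYs %.2f (undisc. %.2f), LYs %.2f (undisc. %.2f)\n",
              x$qaly_discounted, x$qaly_undiscounted,
              x$ly_discounted, x$ly_undiscounted))
  cat(sprintf("  cost €%.0f = acquisition €%.0f + monitoring €%.0f + events €%.0f\n",
              x$cost_total, x$cost_acquisition, x$cost_monitoring, x$cost_events))
  cat(sprintf("  strokes %.2f, bleeds %.2f per patient\n",
              x$expected_strokes, x$expected_bleeds))
  invisible(x)
}

#' Expected lifetime event counts from a cohort trace
#'
#' Undiscounted expected events per patient: the sum over cycles of the
#' incident-event fractions. `strokes` combines major and minor ischemic
#' strokes; `bleeds` combines intracranial with major and minor extracranial
#' bleeds.
#'
#' @param trace An `afcea_trace`.
#' @return Named numeric vector: one entry per event type plus `strokes` and
#'   `bleeds`.
#' @export
expected_event_counts <- function(trace) {
  tot <- colSums(trace$incidence)
  c(tot,
    strokes = tot[["major_is"]] + tot[["minor_is"]],
    bleeds = tot[["ic"]] + tot[["minor_ec"]] + tot[["major_ec"]])
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' Classifies the new strategy against the comparator: dominant when cheaper
#' and more effective, dominated when costlier and less effective, otherwise
#' an incremental cost-effectiveness ratio (per QALY and per life-year). A
#' zero QALY difference with a non-zero cost difference is classified by cost
#' sign with an undefined ICER.
#'
#' @param new `afcea_result` for the new strategy (rivaroxaban).
#' @param comparator `afcea_result` for the comparator (VKA).
#' @return An object of class `afcea_incremental`: list with `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `classification` (`"dominant"`, `"dominated"`
#'   or `"icer"`), `icer_qaly` and `icer_ly` (`NA` unless classified as an
#'   ICER).
#' @export
incremental_analysis <- function(new, comparator) {
  dc <- new$cost_total - comparator$cost_total
  dq <- new$qaly_discounted - comparator$qaly_discounted
  dl <- new$ly_discounted - comparator$ly_discounted
  if (dq > 0 && dc < 0) {
    cls <- "dominant"; icer_q <- NA_real_; icer_l <- NA_real_
  } else if (dq < 0 && dc > 0) {
    cls <- "dominated"; icer_q <- NA_real_; icer_l <- NA_real_
  } else if (dq == 0) {
    cls <- if (dc < 0) "dominant" else if (dc > 0) "dominated" else "icer"
    icer_q <- if (dc == 0) 0 else NA_real_
    icer_l <- icer_q
  } else {
    cls <- "icer"
    icer_q <- dc / dq
    icer_l <- if (dl != 0) dc / dl else NA_real_
  }
  structure(list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 classification = cls, icer_qaly = icer_q, icer_ly = icer_l),
            class = "afcea_incremental")
}

#' @export
print.afcea_incremental <- function(x, ...) {
  cat(sprintf("<afcea_incremental> Δcost €%.0f, ΔQALY %.3f, ΔLY %.3f: %s",
              x$delta_cost, x$delta_qaly, x$delta_ly, x$classification))
  if (x$classification == "icer" && is.finite(x$icer_qaly))
    cat(sprintf(" (€%.0f/QALY)", x$icer_qaly))
  cat("\n")
  invisible(x)
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accumulate_outcomes()].
#'
#' @inheritParams run_cohort
#' @return An `afcea_result`.
#' @export
run_strategy <- function(strategy, params) {
  accumulate_outcomes(run_cohort(strategy, params), params)
}

#' Run the pairwise base-case comparison
#'
#' Runs both strategies on one parameter set and performs the incremental
#' analysis of rivaroxaban versus VKA.
#'
#' @param params Validated parameter set (defaults to the bundled base case).
#' @return List with `riva`, `vka` (each an `afcea_result`) and `incremental`
#'   (an `afcea_incremental`).
#' @export
run_comparison <- function(params = base_case_parameters()) {
  riva <- run_strategy("riva", params)
  vka <- run_strategy("vka", params)
  list(riva = riva, vka = vka, incremental = incremental_analysis(riva, vka))
}

#' Results table for export
#'
#' @param results List as returned by [run_comparison()].
#' @return A data.frame with one row per strategy and columns matching the
#'   `afcea_result` fields.
#' @export
results_as_data_frame <- function(results) {
  row <- function(x) data.frame(
    strategy = x$strategy,
    qaly_discounted = x$qaly_discounted, ly_discounted = x$ly_discounted,
    qaly_undiscounted = x$qaly_undiscounted, ly_undiscounted = x$ly_undiscounted,
    cost_total = x$cost_total, cost_acquisition = x$cost_acquisition,
    cost_monitoring = x$cost_monitoring, cost_events = x$cost_events,
    expected_strokes = x$expected_strokes, expected_bleeds = x$expected_bleeds)
  rbind(row(results$riva), row(results$vka))
}
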