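# One-way sensitivity analysis, named scenarios, probabilistic sensitivity
# analysis and the cost-effectiveness acceptability curve.

#' Lognormal parameters from a relative-risk point estimate and 95% CI
#'
#' @param point Relative-risk point estimate (> 0).
#' @param lo,hi 95% confidence bounds, `0 < lo <= point <= hi`.
#' @return List with `location = log(point)` and
#'   `scale = (log(hi) - log(lo)) / (2 * 1.959964)` on the log scale.
#' @export
lognormal_from_ci <- function(point, lo, hi) {
  for (v in c(point, lo, hi)) {
    chk_number(v, "lognormal_from_ci")
    if (v <= 0) afcea_stop("lognormal_from_ci", "bounds must be positive")
  }
  if (!(lo <= point && point <= hi))
    afcea_stop("lognormal_from_ci", "requires lo <= point <= hi")
  list(location = log(point), scale = (log(hi) - log(lo)) / (2 * stats::qnorm(0.975)))
}

#' Method-of-moments parameters for beta and gamma distributions
#'
#' Beta: `alpha = m * ((m * (1 - m)) / v - 1)`, `beta = alpha * (1 - m) / m`.
#' Gamma: `shape = m^2 / v`, `scale = v / m`. The resulting distributions
#' reproduce the requested mean and standard deviation exactly.
#'
#' @param family `"beta"` or `"gamma"`.
#' @param mean Target mean (in `(0, 1)` for beta, positive for gamma).
#' @param se Target standard deviation (> 0). For beta it must satisfy
#'   `se^2 < mean * (1 - mean)`.
#' @return Named list of family parameters (`shape1`/`shape2` for beta,
#'   `shape`/`scale` for gamma).
#' @export
moment_match <- function(family = c("beta", "gamma"), mean, se) {
  family <- match.arg(family)
  chk_number(mean, "mean"); chk_number(se, "se")
  if (se <= 0) afcea_stop("se", "must be positive")
  v <- se^2
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) afcea_stop("mean", "beta mean must be in (0, 1)")
    if (v >= mean * (1 - mean))
      afcea_stop("se", sprintf("infeasible beta variance: se^2 = %g >= mean*(1-mean) = %g",
                               v, mean * (1 - mean)))
    a <- mean * ((mean * (1 - mean)) / v - 1)
    list(shape1 = a, shape2 = a * (1 - mean) / mean)
  } else {
    if (mean <= 0) afcea_stop("mean", "gamma mean must be positive")
    list(shape = mean^2 / v, scale = v / mean)
  }
}

param_get <- function(params, path) {
  cur <- params
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(cur[[k]])) afcea_stop(path, "unknown parameter path")
    cur <- cur[[k]]
  }
  cur
}

param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- paste0("params", paste0("[['", keys, "']]", collapse = ""))
  param_get(params, path)  # errors on unknown path
  eval(parse(text = paste0(expr, " <- value")))
  params
}

#' Default probabilistic sensitivity analysis distribution specification
#'
#' One entry per uncertain parameter: beta distributions for baseline
#' per-cycle risks (both treatment lines), case fatalities, post-event excess
#' mortality and utilities; lognormal distributions for the relative risks,
#' parameterised from their published 95% confidence intervals; gamma
#' distributions for acute and follow-up event costs. Parameters without a
#' published confidence interval receive a standard error of 20% of the mean
#' (a conventional assumption, configurable via `default_se_frac`). The VKA
#' treatment disutility is sampled as a beta-distributed decrement
#' (`value = 1 - draw`). Structural-zero parameters are left fixed.
#'
#' @param params Validated parameter set.
#' @param default_se_frac Standard error as a fraction of the mean for
#'   parameters without published uncertainty (default 0.2).
#' @return A data-frame-free list of specs, each
#'   `list(path, family, args...)`, consumed by [run_psa()].
#' @export
default_psa_specs <- function(params, default_se_frac = 0.2) {
  specs <- list()
  add <- function(path, family, ...) {
    specs[[length(specs) + 1L]] <<- c(list(path = path, family = family),
                                      list(...))
  }
  beta_path <- function(path) {
    m <- param_get(params, path)
    if (m > 0 && m < 1) add(path, "beta", mean = m, se = default_se_frac * m)
  }
  gamma_path <- function(path) {
    m <- param_get(params, path)
    if (m > 0) add(path, "gamma", mean = m, se = default_se_frac * m)
  }
  for (blk in c("event_rates_vka", "event_rates_secondline"))
    for (k in EVENT_KEYS) beta_path(paste(blk, k, sep = "."))
  for (k in RR_KEYS) {
    rr <- params$effect[[k]]
    add(paste0("effect.", k, ".point"), "lognormal",
        point = rr$point, lo = rr$lower, hi = rr$upper)
  }
  for (k in names(params$mortality$case_fatality))
    beta_path(paste0("mortality.case_fatality.", k))
  for (k in names(params$mortality$post_excess))
    beta_path(paste0("mortality.post_excess.", k))
  beta_path("utilities.baseline")
  dec <- 1 - params$utilities$vka_multiplier
  if (dec > 0)
    add("utilities.vka_multiplier", "beta_complement",
        mean = dec, se = default_se_frac * dec)
  for (k in names(params$utilities$acute)) beta_path(paste0("utilities.acute.", k))
  for (k in names(params$utilities$post)) beta_path(paste0("utilities.post.", k))
  for (k in names(params$costs$acute)) gamma_path(paste0("costs.acute.", k))
  for (k in names(params$costs$followup)) gamma_path(paste0("costs.followup.", k))
  specs
}

draw_spec <- function(spec) {
  switch(spec$family,
    fixed = spec$value,
    beta = {
      p <- moment_match("beta", spec$mean, spec$se)
      stats::rbeta(1, p$shape1, p$shape2)
    },
    beta_complement = {
      p <- moment_match("beta", spec$mean, spec$se)
      1 - stats::rbeta(1, p$shape1, p$shape2)
    },
    gamma = {
      p <- moment_match("gamma", spec$mean, spec$se)
      stats::rgamma(1, shape = p$shape, scale = p$scale)
    },
    lognormal = {
      lp <- lognormal_from_ci(spec$point, spec$lo, spec$hi)
      stats::rlnorm(1, lp$location, lp$scale)
    },
    afcea_stop("family", paste("unknown distribution family", spec$family)))
}

#' Run the probabilistic sensitivity analysis
#'
#' Each iteration draws every uncertain parameter from its specification,
#' runs both strategies through the cohort model, and records the incremental
#' cost and QALY pair. Identical `(seed, n_iterations)` give bit-identical
#' output.
#'
#' @param params Validated base parameter set.
#' @param specs Distribution specifications (default
#'   [default_psa_specs()]).
#' @param n_iterations Number of Monte-Carlo iterations.
#' @param seed Integer seed.
#' @return An object of class `afcea_psa`: data.frame with one row per
#'   iteration (`draw`, `delta_cost`, `delta_qaly`, `cost_riva`, `cost_vka`,
#'   `qaly_riva`, `qaly_vka`, `dominant`).
#' @export
run_psa <- function(params, specs = default_psa_specs(params),
                    n_iterations = 1000L, seed = 1L) {
  stopifnot(inherits(params, "afcea_parameters"), n_iterations >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    p <- params
    for (spec in specs) p <- param_set(p, spec$path, draw_spec(spec))
    riva <- run_strategy("riva", p)
    vka <- run_strategy("vka", p)
    dc <- riva$cost_total - vka$cost_total
    dq <- riva$qaly_discounted - vka$qaly_discounted
    if (!is.finite(dc) || !is.finite(dq))
      warning(sprintf("PSA draw %d produced non-finite outcomes", i))
    rows[[i]] <- data.frame(draw = i, delta_cost = dc, delta_qaly = dq,
                            cost_riva = riva$cost_total, cost_vka = vka$cost_total,
                            qaly_riva = riva$qaly_discounted,
                            qaly_vka = vka$qaly_discounted,
                            dominant = dc < 0 && dq > 0)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("afcea_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the new
#' strategy is cost-effective: the fraction of PSA samples with non-negative
#' net monetary benefit `wtp * delta_qaly - delta_cost >= 0` (ties count as
#' cost-effective).
#'
#' @param samples An `afcea_psa` object (or data.frame with `delta_cost` and
#'   `delta_qaly`).
#' @param wtp_grid Willingness-to-pay thresholds (€/QALY).
#' @return Data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (nrow(samples) == 0) afcea_stop("samples", "no PSA samples")
  if (length(wtp_grid) == 0) afcea_stop("wtp_grid", "empty threshold grid")
  prob <- vapply(wtp_grid, function(l)
    mean(l * samples$delta_qaly - samples$delta_cost >= 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_df Data.frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Default one-way sensitivity plan
#'
#' The tabulated deterministic drivers: VKA maintenance visit frequency,
#' first-cycle and subsequent discontinuation probabilities of both drugs,
#' the VKA utility multiplier, the stroke and myocardial-infarction relative
#' risks (over their 95% CIs), a global multiplier on all rivaroxaban
#' relative risks, VKA visit tariffs (±20%), transport uptake (0-100%) and
#' the fixed-dose therapy visit frequency.
#'
#' @param params Validated parameter set (supplies the base values).
#' @return Data.frame with columns `parameter`, `low`, `high`.
#' @export
default_owsa_plan <- function(params) {
  plan <- rbind(
    c("costs.visits_per_cycle.vka_maintenance", 1, 5),
    c("persistence.disc_subsequent.riva", 0, 0.09),
    c("utilities.vka_multiplier", 0.92, 1.00),
    c("persistence.disc_first_cycle.riva", 0, 0.54),
    c("persistence.disc_subsequent.vka", 0, 0.06),
    c("persistence.disc_first_cycle.vka", 0, 0.31),
    c("effect.rr_mi.point", 0.63, 1.06),
    c("effect.global_rr_multiplier", 0.75, 1.25),
    c("effect.rr_is.point", 0.75, 1.17),
    c("costs.visit.vka_subsequent", 17.69, 26.31),
    c("costs.visit.vka_first", 25.73, 38.27),
    c("costs.transport.uptake", 0, 1),
    c("costs.visits_per_cycle.other", 0, 1))
  data.frame(parameter = plan[, 1], low = as.numeric(plan[, 2]),
             high = as.numeric(plan[, 3]))
}

apply_owsa_value <- function(params, path, value) {
  if (path == "effect.global_rr_multiplier") {
    for (k in RR_KEYS) {
      rr <- params$effect[[k]]
      params$effect[[k]]$point <- rr$point * value
      params$effect[[k]]$lower <- min(rr$lower * value, rr$point * value)
      params$effect[[k]]$upper <- max(rr$upper * value, rr$point * value)
    }
    params
  } else {
    param_set(params, path, value)
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the pairwise comparison with one parameter at its low value, then
#' at its high value, all else at base. For the synthetic path
#' `effect.global_rr_multiplier` the value multiplies every rivaroxaban
#' relative risk (base 1).
#'
#' @param params Validated parameter set.
#' @param plan Data.frame with `parameter` (path), `low`, `high`
#'   (default [default_owsa_plan()]).
#' @param min_icer_change Optional reporting filter: keep only parameters
#'   whose low or high run moves the ICER by more than this amount
#'   (dominance is treated as an ICER of 0 for the comparison, mirroring the
#'   convention of reporting only influential drivers).
#' @return Data.frame of class `afcea_owsa` with base/low/high input values
#'   and the classification and ICER at each bound.
#' @export
one_way_sensitivity <- function(params, plan = default_owsa_plan(params),
                                min_icer_change = NULL) {
  base_inc <- run_comparison(params)$incremental
  res <- lapply(seq_len(nrow(plan)), function(i) {
    path <- plan$parameter[i]
    base_value <- if (path == "effect.global_rr_multiplier") 1
                  else param_get(params, path)
    if (!(plan$low[i] <= base_value && base_value <= plan$high[i]))
      afcea_stop(path, "requires low <= base <= high")
    one <- function(v) {
      inc <- run_comparison(apply_owsa_value(params, path, v))$incremental
      list(class = inc$classification, icer = inc$icer_qaly)
    }
    lo <- one(plan$low[i]); hi <- one(plan$high[i])
    data.frame(parameter = path, base = base_value,
               low = plan$low[i], high = plan$high[i],
               class_low = lo$class, icer_low = lo$icer,
               class_high = hi$class, icer_high = hi$icer)
  })
  out <- do.call(rbind, res)
  if (!is.null(min_icer_change)) {
    as_icer <- function(cls, icer) ifelse(cls == "icer", icer, 0)
    base_icer <- as_icer(base_inc$classification, base_inc$icer_qaly)
    chg <- pmax(abs(as_icer(out$class_low, out$icer_low) - base_icer),
                abs(as_icer(out$class_high, out$icer_high) - base_icer))
    out <- out[chg > min_icer_change, , drop = FALSE]
  }
  class(out) <- c("afcea_owsa", "data.frame")
  out
}

SCENARIOS <- c("sot_aspirin", "itt_aspirin", "sot_none", "itt_none",
               "no_vka_disutility", "rebate_9", "rebate_14")

#' Apply a named scenario to a parameter set
#'
#' \describe{
#'   \item{sot_aspirin}{the base case (safety-on-treatment effects, switch to
#'     aspirin).}
#'   \item{itt_aspirin}{intention-to-treat relative risks for stroke,
#'     myocardial infarction and systemic embolism (bleeding effects are
#'     safety endpoints and keep their on-treatment estimates).}
#'   \item{sot_none / itt_none}{discontinuing patients switch to no treatment
#'     (second-line event rates from [secondline_event_rates()] with
#'     `kind = "none"`).}
#'   \item{no_vka_disutility}{no treatment-related disutility on VKA.}
#'   \item{rebate_9 / rebate_14}{9% positive-list entry rebate, alone or with
#'     the additional 5% volume rebate, applied to drug acquisition.}
#' }
#'
#' @param name Scenario name.
#' @param params Base parameter set.
#' @return The modified, validated parameter set.
#' @export
scenario_parameters <- function(name, params = base_case_parameters()) {
  if (!name %in% SCENARIOS)
    afcea_stop("name", paste("unknown scenario; valid:",
                             paste(SCENARIOS, collapse = ", ")))
  p <- unclass(params)
  if (name %in% c("itt_aspirin", "itt_none")) {
    for (k in names(p$effect$itt)) p$effect[[k]] <- p$effect$itt[[k]]
    p$effect$population <- "ITT"
  }
  if (name %in% c("sot_none", "itt_none")) {
    p$persistence$second_line <- "none"
    p$event_rates_secondline <- secondline_event_rates(p$event_rates_vka, "none")
    p$costs$drug_daily$secondline <- 0
    p$costs$visits_per_cycle$secondline <- 0
  }
  if (name == "no_vka_disutility") p$utilities$vka_multiplier <- 1
  if (name == "rebate_9") p$costs$rebate$entry <- 0.09
  if (name == "rebate_14") p$costs$rebate <- list(entry = 0.09, volume = 0.05)
  validate_parameters(p)
}

#' Run a named scenario analysis
#'
#' @inheritParams scenario_parameters
#' @return List with `name`, `riva`, `vka` and `incremental` as in
#'   [run_comparison()].
#' @export
run_scenario <- function(name, params = base_case_parameters()) {
  out <- run_comparison(scenario_parameters(name, params))
  out$name <- name
  out
}
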