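# Cohort engine: state space, per-cycle transition probabilities, and the
# lifetime evolution of the cohort distribution.

ALIVE_STATES <- c("stable_af",
                  "acute_major_is", "acute_minor_is", "acute_se", "acute_mi",
                  "acute_minor_ec", "acute_major_ec", "acute_ic",
                  "post_major_is", "post_minor_is", "post_mi", "post_ic")

DEAD_STATES <- c("dead_event", "dead_other")

# events competing in each cycle; ischemic stroke is split into major/minor
# by settings$stroke_major_fraction
EVENTS <- c("major_is", "minor_is", "se", "mi", "minor_ec", "major_ec", "ic")

# chronic sequel of each permanent event; transient events resolve back to
# the state they arose from
PERMANENT_EVENT_POST <- c(major_is = "post_major_is", minor_is = "post_minor_is",
                          mi = "post_mi", ic = "post_ic")

# severity ranking used by the single-chronic-state overwrite rule
POST_RANK <- c(post_major_is = 4, post_ic = 3, post_mi = 2, post_minor_is = 1)

#' Ordered compartment list of the cohort model
#'
#' Every alive health state exists once per treatment line (first line: the
#' strategy drug; second line: aspirin or no treatment after permanent
#' discontinuation); the two death states are shared. The ordering is fixed
#' and deterministic.
#'
#' @return Character vector of 26 compartment labels, `"state|line"` for the
#'   alive states plus `"dead_event"` and `"dead_other"`.
#' @export
build_state_space <- function() {
  c(as.vector(outer(ALIVE_STATES, c("first", "second"), paste, sep = "|")),
    DEAD_STATES)
}

#' Background other-cause mortality for one cycle
#'
#' Looks up the annual all-cause death probability at the (completed-year)
#' age and converts it to the 3-month cycle with [annual_to_cycle_prob()].
#' At and beyond the life table's terminal age the probability is 1.
#'
#' @param age Age in years (may be fractional; the annual probability of the
#'   completed year applies).
#' @param life_table List with `ages` and `qx` as in the parameter set.
#' @return Per-cycle death probability.
#' @export
background_mortality_cycle <- function(age, life_table) {
  a <- floor(age)
  if (a < life_table$ages[1])
    afcea_stop("age", sprintf("age %g below life table start %d", a,
                              life_table$ages[1]))
  idx <- a - life_table$ages[1] + 1L
  q <- if (idx > length(life_table$qx)) 1 else life_table$qx[[idx]]
  annual_to_cycle_prob(q)
}

#' Discount multiplier for a model cycle
#'
#' @param cycle_index Zero-based cycle index (the first cycle is undiscounted).
#' @param annual_rate Annual discount rate (same rate for costs and outcomes).
#' @return `(1 + annual_rate)^(-cycle_index / 4)`.
#' @export
discount_factor <- function(cycle_index, annual_rate) {
  if (any(cycle_index < 0)) afcea_stop("cycle_index", "must be >= 0")
  chk_nonneg(annual_rate, "annual_rate")
  (1 + annual_rate)^(-cycle_index / 4)
}

# per-cycle event probabilities (7 events) for one treatment line
line_event_rates <- function(params, strategy, line) {
  tab <- if (line == "first") params$event_rates_vka else params$event_rates_secondline
  f_major <- params$settings$stroke_major_fraction
  r <- c(major_is = tab$ischemic_stroke * f_major,
         minor_is = tab$ischemic_stroke * (1 - f_major),
         se = tab$systemic_embolism,
         mi = tab$myocardial_infarction,
         minor_ec = tab$minor_extracranial_bleed,
         major_ec = tab$major_extracranial_bleed,
         ic = tab$intracranial_bleed)
  if (line == "first" && strategy == "riva") {
    eff <- params$effect
    rr <- c(major_is = eff$rr_is$point, minor_is = eff$rr_is$point,
            se = eff$rr_se$point, mi = eff$rr_mi$point,
            minor_ec = eff$rr_minor_ec$point, major_ec = eff$rr_major_ec$point,
            ic = eff$rr_ic$point)
    r[] <- treated_event_probability(r, rr)
  }
  r
}

case_fatality_vector <- function(mortality) {
  cf <- mortality$case_fatality
  c(major_is = cf$major_is, minor_is = cf$minor_is, se = cf$se, mi = cf$mi,
    minor_ec = cf$minor_ec, major_ec = cf$major_ec, ic = cf$ic)
}

# Build the one-cycle transition matrix P (compartments x compartments) and
# the incidence-rate matrix E (compartments x events). E[s, e] is the
# probability that an occupant of s experiences event e during the cycle,
# whether the event routes through an acute tunnel or is absorbed in place.
build_cycle_matrices <- function(params, strategy, bg, first_cycle, disc_active) {
  comp <- build_state_space()
  n <- length(comp)
  P <- matrix(0, n, n, dimnames = list(comp, comp))
  E <- matrix(0, n, length(EVENTS), dimnames = list(comp, EVENTS))

  cf <- case_fatality_vector(params$mortality)
  excess <- params$mortality$post_excess
  pe <- params$persistence
  ic_disc <- pe$ic_bleed_discontinuation_prob

  for (line in c("first", "second")) {
    r <- line_event_rates(params, strategy, line)
    disc <- if (line != "first" || !disc_active) 0
            else if (first_cycle) pe$disc_first_cycle[[strategy]]
            else pe$disc_subsequent[[strategy]]
    other_line <- if (line == "first") "second" else "first"
    cl <- function(s) paste(s, line, sep = "|")           # this line
    ol <- function(s) paste(s, other_line, sep = "|")

    # -- stable: competing acute events to tunnels, background death,
    #    discontinuation of event-free survivors, remainder stays
    src <- cl("stable_af")
    exit <- sum(r) + bg
    scale <- if (exit > 1) 1 / exit else 1
    for (e in EVENTS) P[src, cl(paste0("acute_", e))] <- r[[e]] * scale
    P[src, "dead_other"] <- bg * scale
    free <- max(0, 1 - exit * scale)
    P[src, ol("stable_af")] <- P[src, ol("stable_af")] + free * disc
    P[src, src] <- P[src, src] + free * (1 - disc)
    E[src, ] <- r * scale

    # -- acute tunnels: case fatality, background death, survivors resolve
    for (e in EVENTS) {
      src <- cl(paste0("acute_", e))
      exit <- cf[[e]] + bg
      scale <- if (exit > 1) 1 / exit else 1
      P[src, "dead_event"] <- cf[[e]] * scale
      P[src, "dead_other"] <- bg * scale
      surv <- max(0, 1 - exit * scale)
      if (e %in% names(PERMANENT_EVENT_POST)) {
        dst <- PERMANENT_EVENT_POST[[e]]
        if (e == "ic" && line == "first") {
          # intracranial bleed survivors come off oral anticoagulation
          P[src, ol(dst)] <- P[src, ol(dst)] + surv * ic_disc
          P[src, cl(dst)] <- P[src, cl(dst)] + surv * (1 - ic_disc)
        } else {
          P[src, cl(dst)] <- P[src, cl(dst)] + surv
        }
      } else {
        # transient event: back to the chronic state it arose from (tunnels
        # are only entered from stable AF; see post-state handling below)
        P[src, cl("stable_af")] <- P[src, cl("stable_af")] + surv
      }
    }

    # -- chronic post-event states: new events compete with excess and
    #    background mortality; a permanent event of higher severity than the
    #    current chronic state overwrites it (via its tunnel); all other
    #    events are absorbed in place (case fatality applies, survivors keep
    #    the more severe chronic label)
    for (s in names(POST_RANK)) {
      src <- cl(s)
      exc <- switch(s, post_major_is = excess$major_is,
                    post_minor_is = excess$minor_is,
                    post_mi = excess$mi, post_ic = excess$ic)
      exit <- sum(r) + exc + bg
      scale <- if (exit > 1) 1 / exit else 1
      stay_extra <- 0
      for (e in EVENTS) {
        p_e <- r[[e]] * scale
        upgrade <- e %in% names(PERMANENT_EVENT_POST) &&
          POST_RANK[[PERMANENT_EVENT_POST[[e]]]] > POST_RANK[[s]]
        if (upgrade) {
          P[src, cl(paste0("acute_", e))] <- P[src, cl(paste0("acute_", e))] + p_e
        } else {
          P[src, "dead_event"] <- P[src, "dead_event"] + p_e * cf[[e]]
          surv <- p_e * (1 - cf[[e]])
          if (e == "ic" && line == "first") {
            P[src, ol(s)] <- P[src, ol(s)] + surv * ic_disc
            stay_extra <- stay_extra + surv * (1 - ic_disc)
          } else {
            stay_extra <- stay_extra + surv
          }
        }
      }
      P[src, "dead_event"] <- P[src, "dead_event"] + exc * scale
      P[src, "dead_other"] <- P[src, "dead_other"] + bg * scale
      free <- max(0, 1 - exit * scale)
      P[src, ol(s)] <- P[src, ol(s)] + free * disc
      P[src, src] <- P[src, src] + free * (1 - disc) + stay_extra
      E[src, ] <- r * scale
    }
  }

  P["dead_event", "dead_event"] <- 1
  P["dead_other", "dead_other"] <- 1

  if (any(!is.finite(P)) || any(P < -1e-12))
    stop("parameterization error: negative or non-finite transition probability",
         call. = FALSE)
  list(P = P, E = E)
}

#' Transition probability vector for one compartment
#'
#' Returns the one-cycle transition distribution from a compartment, given
#' the cohort age (which sets background mortality) and the cycle's
#' discontinuation regime. Probabilities sum to 1; if competing exit
#' probabilities would exceed 1 they are proportionally rescaled.
#'
#' @param state Health-state identifier (one of the alive or dead states).
#' @param line `"first"` or `"second"` treatment line (ignored for dead states).
#' @param age Cohort age in years.
#' @param params Validated parameter set.
#' @param strategy `"riva"` or `"vka"`.
#' @param first_cycle Whether the first-cycle discontinuation probability
#'   applies.
#' @param disc_active Whether any non-event discontinuation risk applies this
#'   cycle (it is switched off beyond the persistence horizon).
#' @return Named probability vector over the 26 compartments.
#' @export
transition_probabilities <- function(state, line = "first", age, params,
                                     strategy = c("riva", "vka"),
                                     first_cycle = FALSE, disc_active = TRUE) {
  strategy <- match.arg(strategy)
  comp <- if (state %in% DEAD_STATES) state else paste(state, line, sep = "|")
  if (!comp %in% build_state_space())
    afcea_stop("state", paste("unknown compartment", comp))
  bg <- background_mortality_cycle(age, params$mortality$life_table)
  m <- build_cycle_matrices(params, strategy, bg, first_cycle, disc_active)
  m$P[comp, ]
}

#' Run the lifetime cohort model for one strategy
#'
#' Starts the full cohort in stable AF on first-line therapy at the starting
#' age and iterates 3-month cycles until the terminal age (or until the alive
#' mass falls below `1e-6`). The first cycle applies the first-cycle
#' discontinuation probability; cycles up to the persistence horizon apply
#' the subsequent per-cycle probability; beyond the horizon non-event
#' discontinuation ceases (intracranial-bleed-driven switching always
#' applies). Any mass still alive at the terminal age is forced to other-cause
#' death by the life table's terminal probability of 1.
#'
#' @param strategy `"riva"` or `"vka"` (the first-line drug).
#' @param params Validated parameter set.
#' @return An object of class `afcea_trace`: list with `occupancy`
#'   (cycles x 26 matrix of fractions during each cycle), `incidence`
#'   (cycles x 7 matrix of incident event fractions attributed to the cycle in
#'   which the event is lived through), `ages` (cohort age during each cycle),
#'   `discount` (per-cycle discount factors) and `strategy`.
#' @export
run_cohort <- function(strategy = c("riva", "vka"), params) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "afcea_parameters"))
  comp <- build_state_space()
  start_age <- params$mortality$start_age
  n_cycles <- as.integer(ceiling((params$settings$terminal_age - start_age) * 4)) + 4L
  horizon <- params$persistence$disc_horizon_cycles

  occ <- matrix(0, n_cycles, length(comp), dimnames = list(NULL, comp))
  inc <- matrix(0, n_cycles, length(EVENTS), dimnames = list(NULL, EVENTS))
  occ[1, "stable_af|first"] <- 1
  ages <- start_age + (seq_len(n_cycles) - 1) / 4

  cache <- new.env(parent = emptyenv())
  last <- n_cycles
  for (k in seq_len(n_cycles - 1L)) {
    # deaths during a cycle follow the annual probability of the year of age
    # attained at the cycle's end, so terminal certainty bites exactly at the
    # terminal age
    bg <- background_mortality_cycle(ages[k] + 0.25, params$mortality$life_table)
    first_cycle <- k == 1L
    disc_active <- k <= horizon
    key <- sprintf("%.17g|%d|%d", bg, first_cycle, disc_active)
    m <- cache[[key]]
    if (is.null(m)) {
      m <- build_cycle_matrices(params, strategy, bg, first_cycle, disc_active)
      cache[[key]] <- m
    }
    occ[k + 1L, ] <- occ[k, ] %*% m$P
    inc[k + 1L, ] <- occ[k, ] %*% m$E
    alive <- 1 - occ[k + 1L, "dead_event"] - occ[k + 1L, "dead_other"]
    if (alive < 1e-6) { last <- k + 1L; break }
  }
  occ <- occ[seq_len(last), , drop = FALSE]
  inc <- inc[seq_len(last), , drop = FALSE]
  ages <- ages[seq_len(last)]
  structure(list(occupancy = occ, incidence = inc, ages = ages,
                 discount = discount_factor(seq_len(last) - 1,
                                            params$settings$discount_rate_annual),
                 strategy = strategy),
            class = "afcea_trace")
}

#' @export
print.afcea_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  dead <- x$occupancy[n, "dead_event"] + x$occupancy[n, "dead_other"]
  cat(sprintf("<afcea_trace> strategy %s: %d cycles (age %.2f-%.2f), final dead mass %.4f\n",
              x$strategy, n, x$ages[1], x$ages[n], dead))
  invisible(x)
}

#' Export a cohort trace as a per-cycle data frame
#'
#' One row per cycle with the cohort age, discount factor and the occupancy
#' fraction of every compartment; suitable for writing to CSV.
#'
#' @param trace An `afcea_trace` from [run_cohort()].
#' @return A data.frame with `cycle`, `age`, `discount` and one column per
#'   compartment (with `|` replaced by `.` in names).
#' @export
trace_as_data_frame <- function(trace) {
  occ <- trace$occupancy
  colnames(occ) <- gsub("|", ".", colnames(occ), fixed = TRUE)
  data.frame(cycle = seq_len(nrow(occ)), age = trace$ages,
             discount = trace$discount, occ, check.names = FALSE)
}
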