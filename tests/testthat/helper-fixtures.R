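# Shared helpers: small deterministic parameter sets built in code.

base_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- base_case_parameters()
    cached
  }
})

# flat life table: same annual probability at every age, 1 at the terminal age
flat_life_table <- function(annual, start_age = 75, terminal_age = 110) {
  ages <- seq(start_age, terminal_age)
  list(ages = ages, qx = c(rep(annual, length(ages) - 1), 1))
}

# quiet cohort with no events and constant background mortality; terminal_age
# bounds the run
survival_toy_params <- function(annual_q, terminal_age = 110, discount = 0.035) {
  p <- unclass(make_fixture("no_events"))
  p$mortality$life_table <- flat_life_table(annual_q, terminal_age = terminal_age)
  p$settings$terminal_age <- terminal_age
  p$settings$discount_rate_annual <- discount
  p$persistence$disc_first_cycle <- list(riva = 0, vka = 0)
  p$persistence$disc_subsequent <- list(riva = 0, vka = 0)
  validate_parameters(p)
}

# single-event toy: only ischemic stroke occurs, nobody dies or discontinues
is_only_params <- function(p_is, fmaj = 0.5, terminal_age = 85) {
  p <- unclass(make_fixture("no_death"))
  p$event_rates_vka <- zero_rates <- lapply(p$event_rates_vka, function(x) 0)
  p$event_rates_vka$ischemic_stroke <- p_is
  p$event_rates_secondline <- p$event_rates_vka
  lt <- flat_life_table(0, terminal_age = terminal_age)
  p$mortality$life_table <- lt
  p$settings$terminal_age <- terminal_age
  p$settings$stroke_major_fraction <- fmaj
  p$persistence$disc_first_cycle <- list(riva = 0, vka = 0)
  p$persistence$disc_subsequent <- list(riva = 0, vka = 0)
  validate_parameters(p)
}

table1_vka_rates <- c(ischemic_stroke = 0.0040, myocardial_infarction = 0.0028,
                      systemic_embolism = 0.0005, intracranial_bleed = 0.0019,
                      minor_extracranial_bleed = 0.0297,
                      major_extracranial_bleed = 0.0069)
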