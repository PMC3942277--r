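# afcea

A lifetime Markov cohort cost-utility model comparing first-line
**rivaroxaban** (a fixed-dose direct factor Xa inhibitor) with **vitamin-K
antagonists** (VKA, acenocoumarol) for stroke prevention in non-valvular
atrial fibrillation, from the perspective of a third-party payer (Greek
social insurance, 2013 tariffs). It is intended for health-economics
analysts who need a fully reproducible, scriptable implementation of this
comparison: base case, deterministic scenarios, one-way (tornado)
sensitivity analysis, and probabilistic sensitivity analysis with
cost-effectiveness acceptability curves.

## The model

A cohort enters at age 75 in stable atrial fibrillation on the strategy drug
and moves through 3-month cycles until death (terminal age 110). Each cycle a
patient can suffer one of seven acute complications — major/minor ischemic
stroke (IS), systemic embolism (SE), myocardial infarction (MI), major/minor
extracranial bleeding (EC), intracranial bleeding (IC) — or die of
another cause, discontinue permanently to second-line therapy (aspirin or
nothing), or remain stable. Acute events occupy one-cycle tunnel states
carrying an event utility and a DRG-tariff cost; permanent sequelae are
chronic `post_*` states with excess mortality, reduced utility and
(for major stroke, IC bleed and MI) quarterly follow-up costs. A patient
occupies at most one chronic state, overwritten only by a more severe event
(major IS > IC > MI > minor IS). The state space is 12 alive states × 2
treatment lines + 2 death states = 26 compartments.

Per-cycle event probabilities on VKA come from trial annual rates converted
by `q_cycle = 1 − (1 − q_annual)^(1/4)`; rivaroxaban applies relative risks
multiplicatively. On-VKA time carries a treatment disutility (utility
multiplier 0.95) and an INR monitoring schedule (weekly visits in the first
month, then monthly, with payer-sponsored transport for half of patients);
rivaroxaban needs only routine visits. Costs and QALYs are discounted at
3.5% a year. Strategies are compared by incremental cost per QALY with
dominance classification, and parameter uncertainty is propagated with
beta (risks, utilities), lognormal (relative risks) and gamma (costs)
distributions into a cost-effectiveness acceptability curve
`P(λ·ΔQALY − ΔCost ≥ 0)`.

## Worked example

```r
library(afcea)

params <- base_case_parameters()     # bundled configuration
res <- run_comparison(params)        # both strategies + incremental analysis
res$riva
#> <afcea_result> riva
#>   QALYs 6.50 (undisc. 8.15), LYs 8.55 (undisc. 10.74)
#>   cost €7815 = acquisition €4127 + monitoring €52 + events €3636
#>   strokes 0.23, bleeds 1.31 per patient
res$vka
#> <afcea_result> vka
#>   QALYs 6.24 (undisc. 7.81), LYs 8.47 (undisc. 10.62)
#>   cost €8052 = acquisition €94 + monitoring €3981 + events €3978
#>   strokes 0.23, bleeds 1.26 per patient
res$incremental
#> <afcea_incremental> Δcost €-237, ΔQALY 0.264, ΔLY 0.079: dominant
```

Rivaroxaban buys 0.26 discounted QALYs (mostly by avoiding the VKA
treatment disutility, plus small survival gains from fewer intracranial
bleeds and infarctions) and *saves* €237 per patient: its €4,033 extra drug
acquisition cost is more than offset by €3,928 lower monitoring/transport
cost and €342 lower event-management cost, so it **dominates** VKA.

Scenario, tornado and probabilistic analyses:

```r
run_scenario("itt_aspirin")$incremental       # intention-to-treat effects
tor <- one_way_sensitivity(params)            # tornado table
samples <- run_psa(params, n_iterations = 1000, seed = 1)
ceac(samples, params$settings$wtp_grid)       # acceptability curve
```

A thin command-line launcher with `run`, `owsa`, `psa` and `validate`
subcommands is installed at `inst/cli/afcea`; every run writes a manifest
sufficient to reproduce it.

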