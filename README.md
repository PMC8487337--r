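# ctpta

PK/PD target-attainment simulation and renal-subgroup outcome statistics
for ceftolozane/tazobactam in ventilated nosocomial pneumonia.

## Who this is for

Critically ill patients with hospital-acquired or ventilator-associated
bacterial pneumonia often exhibit **augmented renal clearance** (ARC,
creatinine clearance > 130 mL/min), which accelerates elimination of
renally cleared beta-lactams and could undermine standard dosing. This
package is for pharmacometricians and clinical statisticians who want to
(a) simulate whether the standard ceftolozane/tazobactam regimen (3 g as a
1-h infusion every 8 h) keeps meeting its pharmacodynamic targets in
plasma and pulmonary **epithelial lining fluid (ELF)** across renal
function strata, and (b) reproduce and extend the renal-subgroup outcome
comparisons used in clinical analyses of this question.

## What it computes

**Simulation side.** Steady-state concentrations follow a two-compartment
infusion model (closed-form biexponential superposition) with a
first-order ELF link compartment, dC<sub>ELF</sub>/dt =
k<sub>in</sub>·C<sub>plasma</sub> − k<sub>out</sub>·C<sub>ELF</sub>.
Virtual patients with paired weight/CrCl demographics are drawn per
stratum (normal 80–130; ARC >130–<180, 180–<210, ≥210 capped at
312 mL/min), individualized through covariate and log-normal IIV models,
and scored against the clinical targets: **50% fT>MIC at 4 µg/mL** for
ceftolozane and **35% fT>C<sub>T</sub> at 1 µg/mL** for tazobactam, on
free concentrations (plasma binding 21%/30%, ELF 0%). PTA at a threshold
is the fraction of the cohort attaining.

**Statistics side.** Sex-specific Cockcroft–Gault CrCl
(`(140 − age)·weight/(72·SCr)`, ×0.85 for females), renal categorization,
Wilson score intervals, and **unstratified Newcombe (method 10)
confidence intervals** for differences of proportions, with
half-away-from-zero display rounding and exact inversion of printed
percentages back to counts. The published outcome counts ship as fixtures
(`trial_count_fixtures()`), and `generate_cohort()` builds synthetic
participant tables whose CrCl arises mechanistically from sampled
age/weight/sex/creatinine.

## Worked example

```r
library(ctpta)

# Published microbiologic-cure counts, C/T arm: 70/97 normal vs 55/77 ARC
newcombe_diff_ci(70, 97, 55, 77, label = "micro cure, C/T: normal vs ARC")
#> micro cure, C/T: normal vs ARC (g1_minus_g2): 72.2% vs 71.4%; diff 0.7 pp [-12.4, 14.2]
```

The difference of 0.7 percentage points with a 95% CI spanning zero says
microbiologic cure was comparable between normal renal function and ARC.
The whole packaged comparison table:

```r
build_outcome_table(trial_count_fixtures())[, c("label", "p1_pct", "p2_pct",
  "diff_display", "ci_low_display", "ci_high_display")]
#>             label p1_pct p2_pct diff_display ci_low_display ci_high_display
#> 1      acm_itt_ct   17.7   17.6          0.2           -9.6            10.6
#> 2    acm_itt_mero   17.7   20.3         -2.6          -12.6             7.5
#> 3     cure_itt_ct   57.3   59.4         -2.1          -14.7            10.8
#> 4   cure_itt_mero   59.3   57.5          1.8          -10.6            14.2
#> 5   micro_mitt_ct   72.2   71.4          0.7          -12.4            14.2
#> 6 micro_mitt_mero   75.0   70.0          5.0           -8.7            19.0
```

(Each row's orientation is recorded in the fixture; one published lower
bound differs from the computed value by 0.1 — see the `note` column and
the methods vignette.)

Simulating PTA for the most augmented stratum:

```r
m   <- default_drug_models()$ceftolozane
coh <- sample_stratum(canonical_strata()[["210-312"]], 1000,
                      demographic_model(), seed = 1)
simulate_pta(coh, m, grid = c(1, 2, 4, 8, 16), seed = 1) |>
  subset(matrix == "plasma")
#>         drug stratum matrix threshold   pta    n
#>  ceftolozane 210-312 plasma         1 1.000 1000
#>  ceftolozane 210-312 plasma         2 1.000 1000
#>  ceftolozane 210-312 plasma         4 0.995 1000
#>  ceftolozane 210-312 plasma         8 0.905 1000
#>  ceftolozane 210-312 plasma        16 0.319 1000
```

Even at CrCl 210–312 mL/min, 99.5% of simulated patients meet the
ceftolozane target at the clinical MIC of 4 µg/mL; attainment only decays
at higher MICs. `run_simulate_pta()` / `run_summarize_exposure()` /
`run_compare_outcomes()` / `run_generate_cohort()` are config-driven
wrappers writing CSVs (see `inst/scripts/ctpta.R` for a command-line
front end), and `plot_pta()` draws the four-panel PTA figure.

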