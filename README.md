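# hydroscreen

Statistical pipeline for microtiter-plate screens of [FeFe] hydrogenase
mutants expressed by cell-free protein synthesis (CFPS) from
single-molecule PCR products.

[FeFe] hydrogenases reversibly interconvert H2 with protons and
electrons and are attractive biocatalysts, but they are destroyed by
oxygen. Screening mutant libraries for oxygen tolerance *in vitro*
requires a chain of quantitative steps, each of which this package
implements and tests:

- **Limiting-dilution occupancy** (`occupancy_*`, `estimate_lambda`,
  `consistency_check`): gene counts per well follow a Poisson law with
  mean λ. At the operating point λ = 2.3 about 10% of wells are empty
  (e^−2.3 ≈ 0.100) while 74% of occupied wells hold more than one gene,
  whose signals average. Template concentration is estimated from the
  amplified fraction f by the zero-class (most-probable-number)
  estimator λ̂ = −ln(1 − f), with Clopper–Pearson intervals, and a
  graded-volume plate is checked for cross-volume consistency with a
  likelihood-ratio test under f_i = 1 − exp(−c·V_i).
- **Oxygen deactivation** (`fit_decay`, `volume_for_target`, `o2_dose`):
  residual activity after exposure to a volume V of air-equilibrated
  buffer (~0.25 mM dissolved O2) decays as R(V) = exp(−k·V); the fitted
  k tunes V to the 15–20% residual-activity operating band.
- **Methyl viologen kinetics** (`fit_slope`, `slope_to_mv_rate`,
  `mv_rate_to_h2_rate`, `specific_activity`): A578 time series →
  OLS slope (AU/min) → mM reduced MV/min via a lumped Beer's-law
  coefficient (9.78 AU per mM) → pmol H2/min with 2 electrons per H2 →
  specific activity in pmol H2/min/ng.
- **Hit calling** (`screen_analyze`, `residual_ratio`, `call_hits`):
  the tolerance score is (post/5)/pre (5× more CFPS product is assayed
  post-exposure); wells below a minimum pre-exposure activity are
  disqualified; scores are normalized to each plate's wild-type
  controls and flagged above mean + 2·SD.
- **Power analysis** (`detectable_improvement`, `power_curve`): at a
  2-SD threshold the minimal detectable improvement is 2×CV — 30% at
  CV 15%, 50% at CV 25% — confirmed by Monte-Carlo power curves.
- **Synthetic campaigns** (`simulate_library`, `simulate_screen`,
  `generate_trace`, `run_pipeline`): a fully seeded generator emulating
  Poisson occupancy, within-well signal averaging, lognormal CFPS-yield
  and measurement noise, exponential deactivation, and background
  slopes, so the whole pipeline is testable without wet-lab data.

## Worked example

Estimating template concentration from a graded-volume amplification
plate (three thirds of a 96-well plate receiving 5, 10 and 15 µL of the
same template mix; 31 scored wells each):

```r
library(hydroscreen)
tab <- data.frame(reaction_volume_ul = c(5, 10, 15), n_wells = 31,
                  fraction_amplified = c(0.264, 0.50, 0.623))
estimate_lambda_table(tab, reference_volume = 5)
#>   reaction_volume_ul fraction_amplified lambda_per_reaction    ci_low   ci_high
#> 1                  5              0.264           0.3065252 0.1262029 0.5908324
#> 2                 10              0.500           0.6931472 0.4013824 1.1988339
#> 3                 15              0.623           0.9755101 0.5479558 1.5209711
#>   lambda_per_reference saturated
#> 1            0.3065252     FALSE
#> 2            0.3465736     FALSE
#> 3            0.3251700     FALSE
consistency_check(tab)$p_value
#> [1] 0.9590095
```

The per-reaction estimates (0.31, 0.69, 0.98 molecules) rescale to
0.31, 0.35 and 0.33 molecules per 5 µL; their agreement (LRT p = 0.96)
is the signature of successful single-molecule PCR — amplification
tracks template volume the way single Poisson-distributed molecules
must.

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`:

```
01_dilution_design.R      occupancy design, serial-dilution plan, MPN + LRT
02_oxygen_deactivation.R  decay fit, exposure tuning, parameter recovery
03_simulate_campaign.R    3-plate campaign through traces, QC and hit calls
04_campaign_scale_screen.R  150-plate campaign with a planted 4x mutant
05_power_analysis.R       detectable improvement and power curves
```

For example, `analysis/04_campaign_scale_screen.R` prints:

```
Campaign: 12600 sample wells; 10.2% empty (Poisson predicts 10.0%).
Wild-type residual ratio: mean 0.166 (model 0.165), pooled CV 0.20.
Planted 4x mutant: normalized activity 3.63 -> activity hit: TRUE.
```

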