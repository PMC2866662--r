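---
title: "Models and methods of the cell-free hydrogenase screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the cell-free hydrogenase screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroscreen)
```

# Overview

`hydroscreen` implements the statistics of an *in vitro* screen for
[FeFe] hydrogenase mutants: genes are isolated by limiting dilution,
amplified by single-molecule PCR, expressed by cell-free protein
synthesis (CFPS), and assayed for methyl viologen (MV) turnover before
and after a controlled oxygen exposure. This vignette states each model,
its assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the protocol leaves the design open.

# Poisson occupancy and the zero-class estimator

Template molecules distributed into wells at low concentration follow a
Poisson law: the number of genes in a well is $k \sim \text{Pois}(\lambda)$.
The design trade-off lives entirely in $\lambda$:

* $P(0) = e^{-\lambda}$ wells are empty (wasted capacity);
* among occupied wells, a fraction
  $P(k \ge 2 \mid k \ge 1) = \frac{1 - e^{-\lambda}(1+\lambda)}{1 - e^{-\lambda}}$
  holds several genes whose signals average, raising the improvement a
  mutant needs to be seen.

At the operating point $\lambda = 2.3$, 10.0% of wells are empty and
74.4% of occupied wells are multi-gene. Both directions are exposed:
`occupancy_pmf()` maps $\lambda$ to occupancy, and the zero class maps
an observed amplified fraction back to $\lambda$. Whether the operating
point was chosen from the empty-well criterion or vice versa cannot be
settled from the protocol alone, so neither direction is privileged.

Amplification is treated as a deterministic indicator of at least one
template molecule (no PCR-efficiency or contamination model). The
concentration estimate from an amplified fraction $f$ is the zero-class
(most probable number) estimator $\hat\lambda = -\ln(1-f)$, which is the
binomial maximum-likelihood estimate. Design choices:

* **Confidence intervals.** None are given in the protocol; we use
  Clopper–Pearson intervals on $f$ transformed through $-\ln(1-f)$,
  because exact binomial intervals behave at $f$ near 0 and 1. When only
  a printed percentage is available, counts are recovered by rounding
  $f \cdot n$; without $n$ the interval is `NA`.
* **Saturated rows** ($f = 1$) admit no point estimate; a one-sided
  lower bound is reported with an explicit flag.
* **Wells per section.** A 96-well plate divided into thirds with three
  no-template controls leaves the per-section count ambiguous; we default
  to 31 scored wells per section but make `n_wells` an explicit input,
  and `estimate_lambda()` accepts a fraction directly so printed tables
  reproduce exactly. Printed-value comparisons use ±0.005 on the rounded
  two-decimal scale.
* **Graded-volume consistency.** Sections receiving volumes $V_i$ of one
  template mix share a concentration $c$ under
  $f_i = 1 - e^{-cV_i}$. `consistency_check()` fits $c$ by maximum
  likelihood and compares against the saturated per-row model with a
  likelihood-ratio statistic on $\chi^2_{\text{rows}-1}$. The binomial
  log-likelihood accepts fractional counts (a quasi-likelihood weighted
  by $n$) precisely so tables reconstructed from printed percentages can
  be tested. Simulations at 31 wells/row show the nominal 5% level is
  held to within Monte-Carlo error.
* **Serial dilution planning** uses equal-ratio steps (default 1001×,
  i.e. 1 µL into 1 mL) with the final ratio adjusted to land exactly on
  target. Adsorptive template losses are assumed chemically controlled;
  a per-step `recovery` factor (default 1) is available.

# Oxygen deactivation

Residual activity after a 10-minute incubation with $V$ µL of
air-equilibrated buffer is modelled as

$$R(V) = e^{-kV},$$

with the intercept pinned to 1 because residual activities are already
normalized by the unexposed activity. Choices and caveats:

* The exposure **volume** is the dose variable; the dissolved-O2 time
  profile during the incubation is deliberately not modelled (it is not
  measurable in this format). The nominal dose in nmol is the product
  $V \times 0.25\ \text{mM}$.
* The fit is **nonlinear least squares on the linear scale** (one
  parameter, solved with `nls`), not log-linear regression: taking logs
  inflates noise at small residuals, exactly where the screen operates.
  A log-linear fit is available behind `method = "loglinear"`.
* A free intercept and a non-zero asymptote
  $R(V) = (1-c)e^{-kV} + c$ are selectable but off by default: the
  protocol observes complete oxygen removal within the incubation and no
  oxygen-tolerant fraction.
* Non-positive residuals are excluded (with a warning) where logs are
  needed; identical all-1 residuals return the $k = 0$ boundary with a
  flag rather than an error.
* No tabulated decay observations exist to refit, so the module is
  validated by **parameter recovery**: over $k \in \{0.05, 0.1, 0.2\}$
  /µL and replicate CV up to 20% (3 replicates at 6 volumes), the median
  estimate stays within 5% of truth at CV 10% and mean bias below 10%
  throughout.
* The default decay constant in `screen_config()` is $k = 0.12$/µL, a
  package choice: at the protocol's 15 µL exposure it yields
  $e^{-1.8} = 16.5\%$ residual activity, inside the stated 15–20%
  operating band that balances signal-to-noise against sensitivity to
  exposure variation. `volume_for_target()` inverts the fitted curve,
  $V^* = -\ln(\text{target})/k$.

# Methyl viologen kinetics and units

In the H2-consumption direction the enzyme reduces MV with electrons
from H2; reduced MV is blue, so A578 rises linearly while MV is in
excess. The unit chain is:

$$\text{AU/min} \xrightarrow{\div 9.78} \text{mM MV/min}
  \xrightarrow{\times V_{\text{assay}} \times 10^3 / 2} \text{pmol H}_2\text{/min}
  \xrightarrow{\div \text{ng}} \text{pmol H}_2\text{/min/ng}.$$

* The printed conversion coefficient "9.78 AU/min/mM" has inconsistent
  units as written; we interpret it as a **lumped, path-length-inclusive
  conversion of 9.78 AU per mM** of reduced MV, a single configurable
  constant. Whether it assumes a 1 cm cuvette or folds in the plate
  geometry is not distinguishable and does not need to be.
* Stoichiometry: 2 single-electron MV reductions per H2, exposed as
  `electrons_per_h2`.
* Slopes are ordinary least squares over the full 2-minute read, the
  protocol's procedure. $R^2 < 0.9$ flags nonlinearity; an optional
  initial-linear-window selector (best prefix of ≥ 5 points) handles
  saturating traces but is off by default. Flat traces have undefined
  $R^2$ (`NA`), not a nonlinearity flag.
* Negative slopes are permitted and flagged background-dominated, not
  errors: inactive wells drift.
* Specific activity is rate / protein mass; protein mass enters as a
  number (ng). The radiolabel counting chemistry that produces it is out
  of scope, but `protein_mass_from_counts()` provides the pure
  arithmetic with all parameters user-supplied. Specific activities are
  only compared between samples whose protein yields are within a
  similarity band (default ±25%), and `fold_improvement()` refuses
  cross-direction comparisons.

# The synthetic-data generator

`simulate_library()` and `simulate_screen()` generate campaigns with the
statistical structure the analysis assumes — they are the package's test
bed, not a claim about the real library:

* **Effects.** A mutant is inactive with probability 0.3 (a plausible
  knockout rate at 2–10 nucleotide changes per gene); active mutants get
  lognormal multiplicative factors on activity (median 1, sdlog 0.2) and
  on deactivation rate (meanlog 0.05, sdlog 0.05). These distributions
  are **invented stand-ins**: the real effect-size spectrum is unknown.
  The tolerance defaults concentrate just above 1 so that substantially
  tolerance-improved mutants are vanishingly rare, mirroring the
  screening campaign's outcome (activity-improved mutants were found;
  tolerance-improved ones were not). All parameters are exposed.
* **Occupancy.** Sample-well gene counts are Poisson($\lambda$); members
  are consumed sequentially from the library. A well's true activity is
  the **mean** of its members' activities — the signal-averaging penalty
  of co-occupancy — and each member deactivates at its own rate during
  exposure.
* **Noise.** CFPS yield and measurement error are separate lognormal
  factors. Only the residual-activity **ratio** pins them down: yield
  cancels in the ratio, so the two per-read noises are calibrated so the
  ratio of replicate wild-type wells has the configured CV
  (each read has $\text{sdlog} = \sqrt{\log(1+\text{CV}^2)/2}$), and the
  yield factor reuses the same sdlog, splitting a single read's variance
  evenly. The post-read noise carries a meanlog offset making the ratio
  mean-unbiased, so replicate wild-type wells average to $e^{-kV}$ with
  the configured CV — the simulator's calibration contract. Default CV
  is 0.20, the middle of the protocol's 15–25% range.
* **Background.** Every assay adds a small background activity
  (lognormal around 5% of the wild-type signal), so empty wells and
  CAT/no-template controls produce small but non-zero slopes, as real
  extract does.
* **Traces.** `generate_trace()` inverts the assay conversions to emit
  linear A578 ramps with Gaussian read noise (default 0.002 AU/point).
  The default wild-type activity (1500 pmol H2/min/µL, i.e. the 150
  pmol/min/ng reference at a 10 ng/µL soluble yield) implies a
  pre-exposure slope of ~0.15 AU/min, large against read noise — matching
  the protocol, where plate-reader noise is negligible next to
  biological variation. Slopes that would deplete the 2 mM MV pool
  within the read are clipped and flagged.
* **Not emulated:** sequence-level mutagenesis, smPCR failure and
  contamination, spatial plate effects, assay drift within a read,
  saturating kinetics. Passing tests therefore demonstrate the
  *statistical machinery* — estimators, normalization, thresholds,
  power — not robustness to artefacts the generator does not produce.

All randomness flows from explicit integer seeds; a fixed seed gives
byte-identical output, which the pipeline's manifest (config hash plus
per-file checksums) makes auditable.

# Hit calling

Per plate: the tolerance score of a well is
$(\text{post}/5)/\text{pre}$ — five times as much CFPS product is
assayed after exposure, so raw post rates are divided by the volume
factor. Wells with pre-exposure activity below a cutoff are disqualified
(low signal inflates the ratio). Scores are divided by the mean of the
plate's wild-type controls, and a well is a hit when its normalized
score strictly exceeds the wild-type mean plus 2 SD; the activity screen
applies the same rule to normalized pre-exposure activity.

Open choices, resolved as follows:

* **Minimum pre-exposure cutoff**: not stated numerically; default 25%
  of the plate's wild-type mean pre-exposure activity, which sits above
  the control background band (5% of wild type) yet below any
  expression-competent well. Configurable.
* **Threshold statistics** are computed from wild-type control wells per
  plate — the threshold sentence follows the wild-type-replicate CV
  discussion, and replicate experiments show between-day drift that
  per-plate controls exist to absorb. Pooling across plates, and
  computing thresholds from all sample wells, are deliberately not
  defaults.
* **One-tailed, no multiple-testing correction** by default: the 2-SD
  rule is a triage threshold with downstream re-testing, not a
  significance claim. A Bonferroni-adjusted multiplier is available.
* **Ties** at the threshold are not hits (strict inequality).
* A plate with fewer than two usable wild-type controls is rejected
  outright; zero wild-type variance flags the threshold as degenerate.

The decision layer is scale invariant: multiplying all raw activities on
a plate by any constant changes no QC decision, normalized score, or hit
call.

# Detectability and power

With a threshold $m$ SDs above the wild-type mean and wild-type CV $c$,
the smallest improvement whose *expected* normalized score reaches the
threshold is $m \times c$ — 30% at CV 15% and 50% at CV 25% for the
2-SD rule. A mutant at exactly that improvement is detected with
probability one half under symmetric noise. `power_curve()` verifies
this by Monte Carlo and traces the full profile; its default noise model
is symmetric multiplicative normal so the threshold-symmetry property is
exact, with the simulator's lognormal selectable (at screen CVs the two
differ by at most a few percentage points of detection probability).
The null detection probability is the per-tail false-positive rate,
2.3% under the normal approximation; in full simulated screens the
realized rate is somewhat higher because plate thresholds are estimated
from eight controls and the noise is lognormal — visible in the test
suite and a property of any finite-control 2-SD rule.

# Problem sizes and numerical notes

The test suite and analysis scripts choose sizes that keep every run
deterministic and fast while leaving Monte-Carlo error well inside the
asserted tolerances: 500 curves for decay recovery, 10,000 draws per
power-curve point, 300 single-plate campaigns for planted-hit recovery,
a 10-plate campaign (80 wild-type wells) for the simulator round trip,
and a 150-plate campaign in `analysis/04` matching the published scale.
The lognormal ratio has a small upward mean bias
($\sqrt{1+\text{CV}^2}$, about 2% at CV 0.20) relative to $e^{-kV}$
even after the unbiasing offset is applied to a *single* read — the
offset removes it exactly, which is why the calibration places it on
the post read. Fits use `nls` (port algorithm, rate bounded below by
0); "false convergence" reports near flat optima are recorded on the
fit object rather than raised. The zero-class estimator is evaluated
with `log1p` for accuracy at small fractions.

# Known limitations

* The effect-size distributions of the simulated library are stand-ins;
  recall/precision results are statements about the decision layer under
  those distributions, not predictions for any real library.
* Exposure dose is volume, not a kinetic oxygen model; campaigns with
  variable incubation times cannot be compared through $k$.
* The assay model is linear; strongly saturating traces are flagged, and
  the optional initial-window fit is a mitigation, not a kinetic model.
* No spatial (edge/row) plate corrections are provided — the protocol
  relies on wild-type controls only, and so does the package.
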