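---
title: "Modelling Vedolizumab effects on gut permeability and microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Vedolizumab effects on gut permeability and microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vedopkpd)
```

## The model

Vedolizumab is an anti-α4β7-integrin monoclonal antibody used in
inflammatory bowel disease (IBD). It blocks lymphocyte homing to the gut
endothelium by preventing binding to MAdCAM-1, and clinical evidence shows
that treatment is accompanied by recovery of the epithelial barrier
(higher TEER, lower paracellular permeability) and a shift in the faecal
microbiota (rising *Roseburia* abundance). `vedopkpd` ties those
observations together in a deliberately small, transparent model.

Drug disposition is a linear two-compartment system. With central
concentration $C_1$ (mg/L, volume $V_1$), peripheral concentration $C_2$
(volume $V_2$), exchange flow $Q_b$ and first-order elimination $K$ from
the peripheral compartment:

$$\frac{dC_1}{dt} = \frac{Q_b}{V_1}(C_2 - C_1), \qquad
  \frac{dC_2}{dt} = \frac{Q_b}{V_2}(C_1 - C_2) - K C_2.$$

The intestinal compartment carries no drug mass balance of its own: the
effective MAdCAM-1 concentration responds algebraically to $C_2$ through a
Hill (Emax) relationship,

$$M(t) = M_0\left(1 - \frac{E_{max}\,C_2^{\gamma}}
  {E_{50}^{\gamma} + C_2^{\gamma}}\right),$$

so $M$ is bounded between $M_0(1-E_{max})$ and $M_0$ and decreases
monotonically with $C_2$. We implement $M$ as a pointwise function of
$C_2(t)$ with no lag: the source description of the relationship is
instantaneous ("directly influenced by drug concentration in the
peripheral blood"), and a one-step-lagged variant would in any case differ
by $O(h)$ only.

### Parameters and units

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| $Q_b$ | 0.12 | L/day | inter-compartment blood flow |
| $V_1$ | 3.12 | L | central blood volume |
| $V_2$ | 1.65 | L | peripheral blood volume |
| $K$ | 0.0368 | day$^{-1}$ | first-order elimination |
| $M_0$ | 2.23e-2 | mg/L | baseline MAdCAM-1 |
| $E_{max}$ | 0.956 | – | maximum fractional suppression |
| $\gamma$ | 0.3512 | – | Hill coefficient |
| $E_{50}$ | 0.093 | mg/L | half-maximum concentration |

Time is measured in days everywhere. The parameter table this
configuration derives from prints the units of $K$ and $Q_b$ as
"g$^{-1}$" and "L/g"; those are dimensionally impossible in the
differential equations above, and $K = 0.0368$ day$^{-1}$ implies a
half-life of ln 2/0.0368 ≈ 18.8 days — squarely inside the 14–21-day
terminal half-lives reported for the antibody. We therefore read both as
per-day quantities and treat the printed units as typographical errors.

### Dosing and initial conditions

The clinical regimen is 300 mg IV at weeks 0, 2 and 6 (induction), then
every 8 weeks until week 52 (maintenance); weeks convert to days as
1 week = 7 days. Doses are instantaneous jumps of $D/V_1$ in $C_1$,
applied at the nearest grid point not after the event time. The first
event is special: the model's stated initial condition is
$C_1(0) = 60$ mg/L (not $300/3.12 \approx 96$ mg/L), so
`standard_schedule()` defaults the week-0 event to a direct 60 mg/L
increment; set `first_dose_like_rest: true` in the configuration to treat
it like every other dose. $C_2(0) = 0$.

### Numerics

The system is integrated by the explicit Euler method, the same
first-order scheme used in the original analysis, with default step
$h = 0.01$ day. At that step the trajectory deviates from the exact
solution of the linear system by less than 0.1% in relative terms over a
full 364-day course — far below clinical data resolution — and the tests
verify both that bound and the first-order convergence rate (halving $h$
at least halves the error). The exact solution itself,
`closed_form_two_compartment()`, is an eigen-decomposition of the 2×2
system matrix with a Jordan limiting form for the (measure-zero)
repeated-eigenvalue case, and is used only as a validation oracle; the
tests check it independently against a fine-step Runge–Kutta integration.
With $K = 0$ the Euler scheme conserves $V_1 C_1 + V_2 C_2$ exactly, a
property the tests also exercise.

## Permeability from Ussing-chamber flux

Apparent permeability of a biopsy to the 4 kDa FITC-dextran probe (FD4)
is computed from the transported amount $Q_t$ (pmol) after time $t$ (s)
as

$$P_m = \frac{Q_t\,\delta_m}{S\,t\,C_0},$$

with exchange surface $S = 0.017$ cm², initial donor concentration
$C_0 = 10^4$ pmol/cm³ and membrane thickness
$\delta_m = 2.175\times10^{-3}$ cm, giving cm²/s. Reports conventionally
use $10^{-6}$ cm²/s; `format_pm()` applies that scaling. TEER has no
governing equation here — it enters the analysis purely as data.

## The concentration–response links

Cohort regression produced two log-linear links against the central
concentration expressed in mg/mL:

$$C_b = -0.5750\times10^{-3}\,\ln C_1 + 2.4967\times10^{-2}, \qquad
  P_m = 0.0370\times10^{-6}\,\ln C_1 + 0.9885\times10^{-6}.$$

Two design choices deserve note.

* **The logarithm is natural.** The source prints "log" without a base.
  With ln, the permeability link evaluated at the initial 0.06 mg/mL
  gives $0.884\times10^{-6}$ cm²/s, within 0.2% of the observed
  pre-treatment cohort mean ($0.883\times10^{-6}$); with log10 it misses
  by about 7%. The package adopts ln and tests this anchor.
* **Negative predictions are clamped.** The permeability line crosses
  zero near $C_1 = e^{-\mathrm{intercept/slope}}$; since the link is an
  empirical regression, not a mechanism, predictions below zero are
  clamped to 0 with a warning rather than treated as errors.

`fit_link()` recovers coefficients by ordinary least squares on
$\ln C_1$, reporting the standard coefficient of determination against
the mean-only null. `invert_link()` is the exact closed-form inverse.
`link_time_course()` composes the links with a simulated trajectory,
dividing the model's mg/L by 1000 at the interface; grid points with
$C_1 \le 0$ are masked to `NA` and reported, never silently dropped.
Because the permeability slope is positive and the abundance slope
negative, drug washout (falling $C_1$) yields rising *Roseburia*
abundance and falling permeability in parallel — the qualitative time
courses the model exists to reproduce.

Which exact $C_1$ anchors produced the published regressions (pre-dose
troughs versus the initial 60 mg/L, cohort means versus per-patient
values) is not recoverable from the printed record, so the package does
not assert the published $r^2$ values (0.9989, 0.9819); it exposes
`fit_link()` so any anchoring convention can be tried, and tests
coefficient recovery on noiseless data instead.

## Clinical statistics

The analysis layer reproduces the cohort statistics: per-phase summaries
(mean, median, sd with the $n-1$ denominator, min, max), paired
t-tests of baseline versus week 52, and Pearson correlations between the
clinical activity score (Partial Mayo Score in UC, Harvey–Bradshaw Index
in CD) and the Robarts Histopathological Index (RHI).

The correlation convention matters: per-patient, per-phase (score, RHI)
pairs are pooled across the three time points within each disease group.
That convention reproduces the published coefficients exactly — 0.751
for UC over 21 pairs, 0.651 for CD over 12 pairs — and is the one
`run_study_analysis()` adopts.

Tails: tests default to two-tailed. The published CD correlation p-value
(0.011) matches a one-tailed test (two-tailed: 0.022), so the report
carries both one- and two-tailed p-values for correlations rather than
silently choosing. For one-tailed tests the alternative is directional in
the sense of the observed effect.

```{r}
report <- run_study_analysis(fixture_cohort())
report$correlations$UC$two_tailed
report$correlations$CD$one_tailed
report$paired_tests$rhi
```

A single observation yields a degenerate summary (sd reported as 0 with a
flag); a paired test on identical vectors, or a correlation on a constant
vector, is an error rather than a silent NaN.

## The synthetic cohort generator

Only the 11 patients' activity scores and RHI were published per patient;
TEER and permeability appear as phase summaries, and *Roseburia* only
graphically. The generator `generate_cohort()` exists so every pipeline
stage is testable end to end at any cohort size:

* **Endpoint distributions.** TEER, permeability and abundance are drawn
  from zero-truncated normals. Truncation at zero shifts the mean of a
  plain rejection sampler upward (for permeability the published
  mean-to-sd ratio is ≈2, where the shift is material), so the generator
  solves for the underlying normal whose *truncated* distribution has the
  specified mean and sd. The choice of a truncated normal over, say, a
  lognormal is a modelling convenience matching only the published
  mean/sd — no claim is made about higher moments of the real data.
* **Correlated integer scores.** Activity score and RHI are drawn per
  phase from a bivariate Gaussian copula, then rounded and floored at
  zero. The target is the *pooled* correlation across the three phases;
  because the phase means themselves co-trend (both scores fall under
  treatment), the generator back-solves the within-phase copula
  correlation from the between-phase mean trend, and raises an error if
  the requested pooled correlation is infeasible. The rounding/flooring
  discretisation bias is measured by the tests (it stays inside the
  3-standard-error band at n = 2000) rather than corrected.
* **Roseburia phase means** are not published numerically; the defaults
  (0.0266, 0.0277, 0.0289) are derived once by inverting the permeability
  link at the published permeability phase means and evaluating the
  abundance link at the implied concentrations, with an sd of 0.008
  (≈30% coefficient of variation, typical of genus-level relative
  abundances).
* **Determinism.** One spec seed governs everything; each patient draws
  from a substream indexed by patient number, so enlarging a cohort never
  reshuffles earlier patients.

What passing tests on synthetic cohorts do **not** show: the generator
has no within-patient correlation across phases beyond the mean trend, no
disease-specific endpoint differences beyond the score scales, and no
heavy tails — conclusions about real cohorts rest on the fixture data,
not on the generator.

## Problem sizes used in the test suite

The suite simulates one-year trajectories at the default step
(36,400 Euler steps), checks generator moments on one 2000-patient
cohort, and smoke-tests the full generate-then-analyse pipeline across
100 seeds at the clinical cohort size of 11 — sizes chosen to exercise
asymptotics convincingly while keeping the default run quick.

## Known limitations

* The disposition model is a population-average, fixed-parameter model:
  no inter-individual variability, no covariates, no target-mediated
  clearance. It is known to shed drug faster than observed after
  ~week 14 of maintenance.
* The links are static regressions; coupling them to the trajectory
  assumes the cohort relationship holds pointwise in time.
* The induction-phase MAdCAM-1 kinetics are poorly captured by a purely
  algebraic effect model.
* Published summary tables cannot be re-derived from raw data the paper
  trail does not contain (per-patient TEER/permeability); those
  summaries ship as data, and the corresponding significance values
  (e.g. the permeability t0-vs-t2 p = 0.214) are not asserted anywhere.
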