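# vedopkpd

Compartmental PK/PD modelling of Vedolizumab effects on gut barrier
permeability and microbiota in inflammatory bowel disease (IBD).

Vedolizumab is an anti-α4β7-integrin monoclonal antibody used in
ulcerative colitis (UC) and Crohn's disease (CD). Alongside its clinical
effect it restores epithelial barrier function (higher TEER, lower
paracellular permeability to the 4 kDa FITC-dextran probe FD4) and is
accompanied by rising abundance of the butyrate producer *Roseburia*.
This package implements, as a tested pipeline, the quantitative chain
from an IV dosing schedule to those barrier and microbiota endpoints:

1. **Disposition + effect model** — a linear two-compartment IV-bolus
   model with first-order elimination,

   dC₁/dt = (Q_b/V₁)(C₂ − C₁),  dC₂/dt = (Q_b/V₂)(C₁ − C₂) − K·C₂,

   coupled to a Hill (Emax) suppression of intestinal MAdCAM-1,
   M = M₀(1 − E_max·C₂^γ/(E₅₀^γ + C₂^γ)), integrated by explicit Euler
   (`simulate_pkpd()`), with an exact eigen-decomposition solution as
   test oracle (`closed_form_two_compartment()`).
2. **Ussing-chamber permeability** — apparent permeability from raw FD4
   flux, P_m = Q_t·δ_m/(S·t·C₀) (`compute_pm()`).
3. **Concentration–response links** — empirical log-linear regressions
   C_b = −0.575·10⁻³ ln C₁ + 2.4967·10⁻² (Roseburia relative abundance)
   and P_m = 0.037·10⁻⁶ ln C₁ + 0.9885·10⁻⁶ cm²/s, with evaluation,
   OLS fitting, exact inversion and trajectory coupling
   (`eval_link()`, `fit_link()`, `invert_link()`, `link_time_course()`).
4. **Clinical statistics** — cohort summaries, paired t-tests, and
   disease-stratified Pearson correlations between activity scores
   (Partial Mayo Score / Harvey–Bradshaw Index) and the Robarts
   Histopathological Index (`run_study_analysis()`), with the observed
   11-patient cohort shipped as a fixture (`fixture_cohort()`).
5. **Synthetic cohorts** — a seeded generator with the same statistical
   structure (moment-matched zero-truncated endpoints, Gaussian-copula
   correlated integer scores) for end-to-end testing
   (`generate_cohort()`).

It is aimed at modellers and biostatisticians who want a small,
fully-reproducible reference implementation of this treatment-response
pipeline, or a scaffold to refit against a larger cohort.

## Worked example

```r
library(vedopkpd)

# published 11-patient cohort: activity scores + histology
report <- run_study_analysis(fixture_cohort())
report$correlations$UC$two_tailed
#> Pearson r = 0.751  (t = 4.962, df = 19, two-tailed p = 8.657e-05)
report$correlations$CD$two_tailed
#> Pearson r = 0.651  (t = 2.716, df = 10, two-tailed p = 0.02172)
report$paired_tests$rhi
#> paired t = 5.606  (df = 10, two-tailed p = 0.0002258)

# one-year simulation under the clinical regimen, coupled to the links
traj <- simulate_pkpd(t_end = 364, h = 0.01)
tc   <- link_time_course(traj)
```

The correlations say histological inflammation (RHI) tracks the clinical
activity score within each disease group (strongly in UC, moderately in
CD), and the paired t-test says RHI falls significantly between baseline
and week 52 (mean drop 10 points, p < 0.001). In the simulation, drug
washout between doses drives *Roseburia* abundance up and FD4
permeability down in parallel; at the initial concentration
(60 mg/L = 0.06 mg/mL) the permeability link gives

```r
eval_link(permeability_link(), 0.06)
#> [1] 8.844038e-07      # cm^2/s, vs the observed baseline mean 0.883e-6
```

A YAML configuration (`inst/extdata/default_config.yaml`) and a thin
command-line wrapper are provided:

```sh
Rscript scripts/vedopkpd.R simulate --out results/
Rscript scripts/vedopkpd.R analyze  --out results/
```

See the methods vignette (`vignettes/vedolizumab-modelling.Rmd`) for the
model assumptions, unit conventions, generator design and limitations.

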