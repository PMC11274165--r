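# Baseline run configuration: clinical dosing regimen and the cohort-study
# model constants. All values here equal the package defaults; edit a copy
# to explore other regimens or parameter sets.
model:
  pk:
    Qb: 0.12      # inter-compartment blood flow, L/day
    V1: 3.12      # central blood volume, L
    V2: 1.65      # peripheral blood volume, L
    K: 0.0368     # first-order elimination, 1/day
  pd:
    M0: 0.0223    # baseline MAdCAM-1, mg/L
    Emax: 0.956   # maximum fractional suppression
    gamma: 0.3512 # Hill coefficient
    E50: 0.093    # half-maximum drug concentration, mg/L
  schedule:
    dose_mg: 300
    weeks: [0, 2, 6, 14, 22, 30, 38, 46]
    first_increment: 60   # mg/L added at week 0 (set first_dose_like_rest: true to use dose_mg/V1)
  t_end_day: 364
  h_day: 0.01
link:
  roseburia:
    slope: -0.5750e-3
    intercept: 2.4967e-2
  permeability:
    slope: 0.0370e-6
    intercept: 0.9885e-6
synthetic:
  n_patients: 11
  seed: 42
analysis: {}
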