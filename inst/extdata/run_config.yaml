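# Example run configuration reproducing the packaged analysis.
cost_basis: ics
comparisons:
  - ref: A1
    alt: A2
  - ref: B1
    alt: B2
  - ref: A
    alt: B
# 3x China's 2024 per-capita GDP (95,700 CNY)
wtp: 287100
psa:
  n_iterations: 1000
  seed: 42
  cv_fallback: 0.3
  wtp_grid:
    from: 0
    to: 600000
    by: 10000
  pair:
    ref: A
    alt: B
cohort:
  n_patients: null   # study sizes: A1 = 8, A2 = 22, B1 = 21, B2 = 8
  seed: 7
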