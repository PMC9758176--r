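seed: 1
stages: [simulate, ibd, classify, popgen, flux]
simulate:
  scenario: founder_quartet
ibd:
  groups:
    - [P1, P2]
    - [P3, H1]
  max_mismatches: 0
  min_markers: 100
  min_span_bp: 100000
classify:
  input: reference_carriers
popgen:
  counts: cohort_counts.tsv
  population_n: 91800000
flux:
  dimers:
    - [WT, WT]
    - [D207V, D207V]
    - [D207V, catalytic]
    - [catalytic, V603L]
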