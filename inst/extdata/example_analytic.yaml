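# Example: search a seeded 2D analytic torsional surface end to end.
backend: analytic
pes:
  dimension: 2
  seed: 7
  minima_range: [3, 8]
search:
  budget: 150
  e_cut: 2.0
  seed: 11
purge:
  d_tol: 15
  e_tol: 0.01
output: tbo_run
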