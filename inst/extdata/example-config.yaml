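# Desk-scale study configuration (the published study used n_sim = 10000)
scenarios:
  - standard
  - delayed
n_sim: 100
seed: 20240509
out_dir: benefitsim-results
tail_at: estimated      # ASCO tail of curve at 2 x estimated control median
tail_rule: absolute     # bonus needs a >= 50 percentage-point survival gain
directional: true       # significance requires HR point estimate < 1
conditional: true       # summaries over significant trials only
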