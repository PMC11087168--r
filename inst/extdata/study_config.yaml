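# Example study configuration for `planperturb study --spec ...` or
# read_study_config(). All randomness flows from master_seed.
master_seed: 20240314
plans_per_site: 5
parameters:
  - mlc_offset
  - mlc_transmission
  - leaf_tip_width
percentiles: [2.5, 25, 75, 97.5]
resolution: 0.5      # mm per pixel
binary: false        # true = sharp-edged analytic mode (no blur, no T&G)
exclude_pdd: true
percentile_table: percentile_table.yaml
dose_limits: [2, 4]
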