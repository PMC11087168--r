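# Community percentile values (2.5 / 25 / 50 / 75 / 97.5) for the ten
# beam-model parameters. The first three rows are seeded from published
# community data; the remaining rows are PLACEHOLDER spreads - replace them
# with institution- or community-sourced values for quantitative use.
# Units: offset/gain/tip/tg/sigma in cm, curvature 1/cm, transmission and
# the three dosimetric errors as fractions.
mlc_offset: [0.000, 0.017, 0.040, 0.055, 0.116]
mlc_transmission: [0.007, 0.015, 0.018, 0.022, 0.025]
leaf_tip_width: [0.177, 0.200, 0.320, 0.400, 0.500]
mlc_gain: [-0.020, -0.005, 0.000, 0.005, 0.020]
mlc_curvature: [-0.0020, -0.0005, 0.0000, 0.0005, 0.0020]
source_sigma: [0.050, 0.080, 0.100, 0.130, 0.200]
tg_width: [0.020, 0.040, 0.050, 0.070, 0.100]
pdd_slope_err: [-0.004, -0.001, 0.000, 0.001, 0.004]
output_factor_err: [-0.010, -0.003, 0.000, 0.003, 0.010]
off_axis_err: [-0.020, -0.005, 0.000, 0.005, 0.020]
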