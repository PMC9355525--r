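model,sens_pct,spec_pct,auroc,ci_lo,ci_hi
hys_law,67.86,35.07,0.515,0.474,0.555
new_hys_law,82.14,34.55,0.583,0.543,0.623
robles_diaz,57.14,69.79,0.635,0.595,0.673
dsp,78.57,65.45,0.720,0.682,0.756
optimized,75.00,90.45,0.899,0.872,0.922
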