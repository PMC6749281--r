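# Example pipeline configuration (see ?read_config for the schema).
window_t0: 0.5          # epoch start, seconds after cue
window_t1: 2.5          # epoch end, seconds after cue
broadband: [0.5, 40]    # TDP/correlation path bandpass, Hz
filter_order: 4
filterbank: default     # eight 4-Hz bands, 4-36 Hz
rho_grid: [0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9]
cv_folds: 5
cv_repeats: 5
cost: 1.0               # linear classifier margin parameter C
seed: 1
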