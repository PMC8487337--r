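# Default run configuration: packaged calibrated drug models, 1000 virtual
# patients per CrCl stratum, 0.005-h simulation grid.
n_per_stratum: 1000
seed: 1
dt: 0.005
out_dir: ctpta-output
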