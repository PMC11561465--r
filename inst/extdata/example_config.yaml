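# Example kcdyn pipeline configuration (see ?run_config).
seed: 1
n_kc: 60
region_upper: [1200.0, 1200.0, 1200.0]
contact_radius: 12.0
modality: brdu-pulse
analyses: [spatial, turnover]
n_sim: 99
n_perm: 99
clone_n: 1000
output_dir: kcdyn_run
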