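# Example pipeline configuration for becdose::run_pipeline()
# (keys override default_run_config(); sizes kept small for a quick run)
seed: 42
out_dir: becdose-example-run
stages:
- phase1
- dose_time_fit
- qdm
- pkpd
phase1:
  n_per_arm: 8
dose_time_fit:
  n_chains: 2
  n_iter: 1500
  n_burn: 500
pkpd:
  n: 300
  scenarios:
  - disease: CRSwNP
    dose: 100
  - disease: EGPA
    dose: 200
    baseline_fixed: 1.0
  - disease: HES
    dose: 200
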