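# Small demonstration run: three groups, default presets.
# Usage: cfg <- load_run_config(system.file("extdata", "demo_cohort.yaml",
#                                           package = "swersp"))
#        run_pipeline(cfg, "demo_out")
seed: 7
cohort:
  groups:
    - {preset: healthy, n_subjects: 5}
    - {preset: control, n_subjects: 5}
    - {preset: dysphagic, n_subjects: 5}
  n_trials_per_subject: 20
  sampling_rate: 512
  n_channels: 16
preprocess:
  target_rate: 512
  hp_cutoff: 7
  lp_cutoff: 35
  reject_sd: 10
  min_valid_trials: 20
window: {t1: 500, t2: 2000}
f_step: 0.5
correction: none
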