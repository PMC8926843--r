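# Demonstration pipeline configuration: a small two-subject cohort under a
# simulated cholinergic intervention, with two synthetic ROI channels.
seed: 1
output_dir: acttime-demo
stages: [simulate, cox, behavior, roi, report]
task:
  design: balanced
  n_blocks: 2
agent:
  miss_prob: 0.05
  coefficients:
    magRew: 0.3
    ITI: -0.2
experiment:
  n_subjects: 2
  sessions_per_subject: 2
  drug_effect:
    main: 0.5
    iti: 0.0
  experiment: rivastigmine
bold:
  tr: 2.28
  noise_sd: 0.5
  channels:
    BF:
      event: 1.0
      obs_act: 0.5
    ACC:
      event: 1.0
models: [GLM3.2]
roi:
  channel: BF
  glm: GLM2.1
  window: [-4.0, 4.0]
  upsample_dt: 0.1
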