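# Demonstration pipeline configuration: a mid-sized synthetic cohort with
# NDI-only examiner errors, scored by the universal ensemble.
seed: 7
simulation:
  n_screenings: 300
  prevalence: 0.06
  delta: 1.5
  examiner_error_rate: 0.05
  error_mode: ndi_only
model:
  variant: universal
  alt_fields: [subject_age, subject_sex]
  one_topic: drug_abuse
evaluation:
  max_fpr: 0.05
flagging:
  top_frac: 0.05
output:
  write_recordings: false
  write_features: false
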