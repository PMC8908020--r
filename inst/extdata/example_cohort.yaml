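# Example cohort specification for read_cohort_spec(): a reduced two-group
# gait cohort with published covariate magnitudes and three discriminative
# variables. correlation may be "identity" or a full matrix (list of rows).
n_stroke: 31
n_control: 41
confounded: false
correlation: identity
variables:
  - variable: gait_speed
    class: spatiotemporal
    mean_control: 1.3
    sd_control: 0.1
    shift: -4.0
    sd_stroke: 0.3
  - variable: single_support_pct
    class: spatiotemporal
    mean_control: 40.0
    sd_control: 1.7
    shift: -3.5
    sd_stroke: 5.0
  - variable: pelvis_sag_rom
    class: rom
    mean_control: 3.0
    sd_control: 0.8
    shift: 1.9
    sd_stroke: 1.7
  - variable: thorax_frontal_rom
    class: rom
    mean_control: 7.0
    sd_control: 2.5
    shift: 0.0
    sd_stroke: 2.5
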