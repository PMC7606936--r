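ros:
  basal_production: 0.008
  age_production: 0.038
  mito_coupling: 0.35
  tau_coupling: 0.02
  clearance_basal: 1.1
  clearance_K: 0.25
  clearance_weights:
    sod2: 0.15
    skn1: 0.09
    daf16: 0.09
tau:
  production_basal: 0.22
  scenario_multiplier: 1.0
  ros_amplification: 0.45
  ros_K: 0.35
  ros_n: 2.0
  clearance_basal: 0.33
  clearance_weights:
    bec1: 0.04
    uprer_bip: 0.04
nodes:
  uprmt_hsp60:
    basal_drive: 0.35
    input_weight: 0.15
    input_K: 0.3
    input_n: 2.0
    self_feedback_weight: 0.65
    self_feedback_K: 0.6
    self_feedback_n: 6.0
    ros_repression_K: 0.75
    ros_repression_n: 6.0
    tau_repression_K: 1.35
    tau_repression_n: 6.0
    capacity_decline_rate: 0.005
    relaxation_time: 0.5
    expression_scale: 1.0
  uprer_bip:
    basal_drive: 0.35
    input_weight: 0.13
    input_K: 0.5
    input_n: 2.0
    self_feedback_weight: 0.65
    self_feedback_K: 0.6
    self_feedback_n: 6.0
    ros_repression_K: 0.66
    ros_repression_n: 6.0
    tau_repression_K: 0.87
    tau_repression_n: 20.0
    capacity_decline_rate: 0.005
    relaxation_time: 0.5
    expression_scale: 1.0
  uprer_pperk:
    basal_drive: 0.4
    input_weight: 0.3
    input_K: 0.5
    input_n: 2.0
    ros_repression_K: 0.66
    ros_repression_n: 6.0
    tau_repression_K: 0.87
    tau_repression_n: 20.0
    capacity_decline_rate: 0.01
    relaxation_time: 2.0
    expression_scale: 1.0
  skn1:
    basal_drive: 0.25
    input_weight: 0.75
    input_K: 0.3
    input_n: 2.0
    capacity_decline_rate: 0.01
    relaxation_time: 0.5
    expression_scale: 1.0
  daf16:
    basal_drive: 0.25
    input_weight: 0.75
    input_K: 0.35
    input_n: 2.0
    capacity_decline_rate: 0.01
    relaxation_time: 0.5
    expression_scale: 1.0
  sod2:
    basal_drive: 0.3
    skn1_weight: 0.6
    daf16_weight: 0.6
    capacity_decline_rate: 0.01
    relaxation_time: 0.5
    expression_scale: 1.0
  bec1:
    basal_drive: 0.3
    skn1_weight: 0.5
    daf16_weight: 0.5
    mtor_repression_K: 0.6
    mtor_repression_n: 2.0
    capacity_decline_rate: 0.02
    relaxation_time: 0.5
    expression_scale: 1.0
  mtor:
    basal_drive: 0.7
    capacity_decline_rate: 0.03
    relaxation_time: 0.5
    expression_scale: 1.0
  pink1:
    basal_drive: 0.25
    skn1_weight: 0.6
    daf16_weight: 0.6
    capacity_decline_rate: 0.02
    relaxation_time: 0.5
    expression_scale: 1.0
mito:
  damage_rate: 0.24
  damage_K: 0.45
  damage_n: 2.0
  uprmt_protection: 0.45
  uprer_damage_coupling: 1.2
  mitophagy_rate: 1.5
  biogenesis_decline_rate: 0.05
  capacity: 100.0
phenotype:
  activity_cutoff: 0.5
  ros_threshold: 0.38
  tau_threshold: 0.6
  death_hazard: 1.0
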