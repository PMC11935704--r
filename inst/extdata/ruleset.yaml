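# Classification ruleset bundled with sentinelchd.
# Versioned so that refined clinical rule tables can replace it in place.
version: "synthetic-1.0.0"

# Sentinel diagnosis precedence, in order of decreasing clinical complexity.
# When markers of several sentinel diagnoses are pooled for one patient the
# highest-precedence diagnosis wins.
precedence: [HLHS, FUH, TGA, PA, AVSD, TOF, AS, COARCT, VSD]

# Subgroup rules, evaluated in order per diagnosis; the final rule of each
# list is the residual subgroup that always applies.
subgroup_rules:
  HLHS:
    - {subgroup: hlhs}
  FUH:
    - {subgroup: double_inlet_ventricle, any_of: [mod_double_inlet]}
    - {subgroup: tricuspid_atresia}
  TGA:
    - {subgroup: complex_with_PS, all_of: [mod_complex_tga, mod_ps]}
    - {subgroup: complex_without_PS, any_of: [mod_complex_tga]}
    - {subgroup: intact_septum}
  PA:
    - {subgroup: with_VSD, any_of: [dx_vsd]}
    - {subgroup: intact_septum}
  AVSD:
    - {subgroup: tetralogy_AVSD, any_of: [dx_tof]}
    - {subgroup: unbalanced, any_of: [mod_unbalanced_avsd]}
    - {subgroup: partial, any_of: [mod_partial_avsd]}
    - {subgroup: complete}
  TOF:
    - {subgroup: absent_pulm_valve, any_of: [mod_absent_pulm_valve]}
    - {subgroup: DORV, any_of: [mod_dorv]}
    - {subgroup: standard}
  AS:
    - {subgroup: multilevel_LHO, any_of: [mod_multilevel_lho]}
    - {subgroup: isolated}
  COARCT:
    - {subgroup: with_VSD, any_of: [dx_vsd]}
    - {subgroup: isolated}
  VSD:
    - {subgroup: multiple, any_of: [mod_multiple_vsd]}
    - {subgroup: isolated}

# Data-quality rules flagging implausible procedure sequences.
#   q1: stage 2 filled but stage 1 empty, for diagnoses that can follow a
#       staged single-ventricle pathway
#   q2: stage 3 filled but stage 2 empty
#   q3: exclusively biventricular diagnosis with a staged-palliation slot filled
#   q4: indeterminate pathway with both a repair and a stage 2/3 slot filled
#   q5: implausibly late first procedure for the diagnosis (bound in days)
quality_rules:
  q1:
    single_ventricle_diagnoses: [HLHS, FUH, TGA, PA, AVSD]
  q2: {}
  q3:
    biventricular_only: [TOF, AS, COARCT, VSD]
  q4: {}
  q5:
    max_first_age_days:
      HLHS: 365

# Reintervention modality grouping: surgical vs interventional cardiology.
modality_groups:
  surgical: [bypass_surgery, nonbypass_surgery, hybrid]
  catheter: [catheter, electrophysiology]
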