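# Synthetic concept dictionary bundled with sentinelchd.
# This is a shippable stand-in for licensed clinical code lists: raw codes are
# invented, but the structure (diagnosis markers, subgroup modifiers, pathway
# roles per sentinel diagnosis) matches what the phenotyping and pathway rules
# require. Real code lists plug in through this same format.
version: "synthetic-1.0.0"

codes:
  # --- diagnosis marker codes -------------------------------------------
  - {code: "010101", concept: dx_hlhs}
  - {code: "010201", concept: dx_fuh}
  - {code: "010301", concept: dx_tga}
  - {code: "010401", concept: dx_pa}
  - {code: "010501", concept: dx_avsd}
  - {code: "010601", concept: dx_tof}
  - {code: "010701", concept: dx_as}
  - {code: "010801", concept: dx_coarct}
  - {code: "010901", concept: dx_vsd}
  - {code: "010902", concept: dx_vsd}      # legacy alias for the same concept
  - {code: "011001", concept: dx_pda}
  - {code: "011101", concept: dx_asd}
  # --- subgroup modifier codes ------------------------------------------
  - {code: "020101", concept: mod_double_inlet}
  - {code: "020201", concept: mod_tricuspid_atresia}
  - {code: "020301", concept: mod_complex_tga}
  - {code: "020401", concept: mod_ps}
  - {code: "020501", concept: mod_unbalanced_avsd}
  - {code: "020601", concept: mod_partial_avsd}
  - {code: "020701", concept: mod_dorv}
  - {code: "020801", concept: mod_absent_pulm_valve}
  - {code: "020901", concept: mod_multilevel_lho}
  - {code: "021001", concept: mod_multiple_vsd}
  # --- complexity characteristic codes ----------------------------------
  - {code: "030101", concept: cmb_congenital}
  - {code: "030102", concept: cmb_congenital}  # second code, same concept
  - {code: "030201", concept: prem_lt37w}
  # --- procedure codes ---------------------------------------------------
  - {code: "120101", concept: proc_bas}
  - {code: "120201", concept: proc_norwood}
  - {code: "120202", concept: proc_norwood}    # variant code, same concept
  - {code: "120301", concept: proc_hybrid_stage1}
  - {code: "120401", concept: proc_bt_shunt}
  - {code: "120501", concept: proc_pa_band}
  - {code: "120601", concept: proc_glenn}
  - {code: "120701", concept: proc_fontan}
  - {code: "120801", concept: proc_arterial_switch}
  - {code: "120901", concept: proc_tof_repair}
  - {code: "121001", concept: proc_avsd_repair}
  - {code: "121101", concept: proc_vsd_closure}
  - {code: "121201", concept: proc_coarct_repair}
  - {code: "121301", concept: proc_aortic_valvuloplasty}
  - {code: "121401", concept: proc_pa_repair}
  - {code: "121501", concept: proc_transplant}
  - {code: "130101", concept: proc_interventional_cath}
  - {code: "130201", concept: proc_misc_surgery}
  - {code: "130301", concept: proc_ep_ablation}
  - {code: "130401", concept: proc_pacemaker}

diagnosis_markers:
  dx_hlhs: HLHS
  dx_fuh: FUH
  dx_tga: TGA
  dx_pa: PA
  dx_avsd: AVSD
  dx_tof: TOF
  dx_as: AS
  dx_coarct: COARCT
  dx_vsd: VSD
  dx_pda: not_sentinel
  dx_asd: not_sentinel

# Pathway roles per sentinel diagnosis. A concept absent from a diagnosis's
# table has role "other" for that diagnosis. Staged-palliation roles are
# present for every diagnosis so that implausible staged records in
# biventricular-only conditions can still fill slots and trigger quality rules.
roles:
  HLHS:
    proc_bas: prepathway
    proc_norwood: stage1
    proc_hybrid_stage1: stage1
    proc_bt_shunt: stage1
    proc_pa_band: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_transplant: transplant
  FUH:
    proc_bas: prepathway
    proc_norwood: stage1
    proc_hybrid_stage1: stage1
    proc_bt_shunt: stage1
    proc_pa_band: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_transplant: transplant
  TGA:
    proc_bas: prepathway
    proc_bt_shunt: stage1
    proc_pa_band: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_arterial_switch: repair
    proc_transplant: transplant
  PA:
    proc_bas: prepathway
    proc_bt_shunt: stage1
    proc_pa_band: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_pa_repair: repair
    proc_transplant: transplant
  AVSD:
    proc_bas: prepathway
    proc_bt_shunt: stage1
    proc_pa_band: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_avsd_repair: repair
    proc_transplant: transplant
  TOF:
    proc_bas: prepathway
    proc_bt_shunt: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_tof_repair: repair
    proc_transplant: transplant
  AS:
    proc_bas: prepathway
    proc_glenn: stage2
    proc_fontan: stage3
    proc_aortic_valvuloplasty: repair
    proc_transplant: transplant
  COARCT:
    proc_bas: prepathway
    proc_glenn: stage2
    proc_fontan: stage3
    proc_coarct_repair: repair
    proc_vsd_closure: repair
    proc_transplant: transplant
  VSD:
    proc_bas: prepathway
    proc_pa_band: stage1
    proc_glenn: stage2
    proc_fontan: stage3
    proc_vsd_closure: repair
    proc_transplant: transplant

comorbidity_concepts: [cmb_congenital]
prematurity_concepts: [prem_lt37w]
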