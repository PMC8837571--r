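note: 'Synthetic representative virtual patients: parameter sets reconstructed to
  reproduce the documented qualitative phenotypes (VP1 higher/bistable, VP2 control,
  VP3 lower/GR latch, VP4 spurious control, VP5 oscillatory).'
edits_on_default:
  VP1:
    R_CRH_CRH: 6.0
    R0_CRH: -3.161383
    R0_GR: -4.0
    R_GR_CRH: -4.0
    R_CRH_ACTH: 4.0
    R0_ACTH: -2.0
    R_ACTH_COR: 4.0
    R0_COR: -2.0
    R_COR_GR: 2.0
    R_GR_GR: 2.0
    R_GR_ACTH: -4.0
    k_CRH: 2.0
    k_ACTH: 2.0
    k_COR: 2.0
    k_GR: 2.0
  VP2:
    R_CRH_CRH: 3.0
    R0_CRH: -3.161383
    R0_GR: -4.0
    R_GR_CRH: -4.0
    R_CRH_ACTH: 4.0
    R0_ACTH: -2.0
    R_ACTH_COR: 4.0
    R0_COR: -2.0
    R_COR_GR: 2.0
    R_GR_GR: 2.0
    R_GR_ACTH: -4.0
    k_CRH: 2.0
    k_ACTH: 2.0
    k_COR: 2.0
    k_GR: 2.0
  VP3:
    R_CRH_CRH: 2.422
    R0_CRH: -1.31
    R_GR_CRH: -6.163
    R_CRH_ACTH: 7.035
    R0_ACTH: -2.355
    R_GR_ACTH: -2.331
    R_ACTH_COR: 7.973
    R0_COR: -2.903
    R_COR_GR: 3.032
    R_GR_GR: 8.0
    R0_GR: -4.0
    k_CRH: 2.0
    k_ACTH: 2.0
    k_COR: 2.0
    k_GR: 2.0
  VP4:
    R_CRH_CRH: 2.422
    R0_CRH: -1.31
    R_GR_CRH: -6.163
    R_CRH_ACTH: 7.035
    R0_ACTH: -7.0
    R_GR_ACTH: -2.331
    R_ACTH_COR: 7.973
    R0_COR: -2.903
    R_COR_GR: 3.032
    R_GR_GR: 8.0
    R0_GR: -4.0
    k_CRH: 2.0
    k_ACTH: 2.0
    k_COR: 2.0
    k_GR: 2.0
  VP5:
    R_CRH_CRH: 2.422
    R0_CRH: -1.31
    R_GR_CRH: -6.163
    R_CRH_ACTH: 7.035
    R0_ACTH: -2.355
    R_GR_ACTH: -2.331
    R_ACTH_COR: 7.973
    R0_COR: -2.903
    R_COR_GR: 3.032
    R_GR_GR: 4.913
    R0_GR: -4.0
    k_CRH: 2.0
    k_ACTH: 2.0
    k_COR: 2.0
    k_GR: 2.0
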