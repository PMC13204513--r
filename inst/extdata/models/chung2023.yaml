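# Chung 2023 neonatal vancomycin popPK model: one compartment,
# CL = 13.9 * (WT/70) * PMA^0.739/(PMA^0.739 + 47.7^0.739) * (SCr/34)^-0.653,
# V = 65.5 * (WT/70).  Units: L/h, L; covariates kg, weeks, umol/L.
# The residual-error form is configurable; the values below are the package
# defaults used for simulation, not part of the published typical-value model.
name: "Chung 2023"
n_compartments: 1
params:
  cl_L_h:
    base: 13.9
    terms:
      - kind: power
        covariate: weight_kg
        ref: 70
        exponent: 1
      - kind: hill
        covariate: pma_weeks
        tm50: 47.7
        hill: 0.739
      - kind: power
        covariate: scr_umol_L
        ref: 34
        exponent: -0.653
  v_L:
    base: 65.5
    terms:
      - kind: power
        covariate: weight_kg
        ref: 70
        exponent: 1
iiv:
  cl_L_h: 0.1
  v_L: 0.1
residual:
  additive_sd: 2
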