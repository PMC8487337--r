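# Tazobactam default calibrated parameter set (version 1).
# Same structure and units as ceftolozane.yaml.
#
# Anchors: plasma AUC0-8 geometric mean ~61.9 ug.h/mL (CL = 16.155 L/h at
# the reference CrCl) and Cmax ~25.8 ug/mL in the 80-150 mL/min bin;
# ELF/plasma AUC ratio ~0.399 (k_in/k_out); ELF Cmax ~4.7 ug/mL. Omegas
# follow the same rationale as in ceftolozane.yaml (IIV level consistent
# with the published >80%-in-all-strata attainment finding).
drug: tazobactam
regimen:
  dose_mg: 1000
  infusion_h: 1
  interval_h: 8
parameters:
  CL: 16.155        # dose/AUC anchor at the reference CrCl
  V1: 28.7
  Q: 7.0
  V2: 28.7
  k_in: 0.1736      # k_in/k_out = 0.399 = ELF/plasma AUC ratio anchor
  k_out: 0.435
  fu_plasma: 0.70   # 30% bound in plasma
  fu_elf: 1.0       # 0% bound in ELF
covariates:
  crcl_ref: 111     # geometric-mean CrCl of the 80-150 mL/min bin
  cl_crcl_exponent: 0.72
  wt_ref: 80
  v_weight_exponent: 1.0
  pneumonia_v_multiplier: 1.0
  pneumonia_kin_multiplier: 1.0
  pneumonia_kout_multiplier: 1.0
iiv:
  omega_cl: 0.35
  omega_v1: 0.30
  omega_q: 0.25
  omega_v2: 0.25
  omega_kin: 0.30
  omega_kout: 0.30
target:
  threshold_type: C_T
  required_fraction: 0.35   # 35% fT>C_T (restores 1-log kill)
  threshold_value: 1        # ug/mL
elf_driver: total
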