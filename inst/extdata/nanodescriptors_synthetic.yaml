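# SYNTHETIC nanodescriptor registry.
# Real nanomaterial names, invented coefficient values with plausible
# magnitudes; measured nanodescriptors are not redistributed with this
# package and must be supplied by the user in this format.
# log k = c + E*r_e + S*p_s + A*a + B*b + V*v
- enm_id: AlOOH
  c: -0.52
  r_e: 0.41
  p_s: 0.63
  a: -1.21
  b: -2.84
  v: 3.12
- enm_id: TiO2_NM105
  c: -0.34
  r_e: 0.28
  p_s: 0.71
  a: -0.95
  b: -2.61
  v: 2.88
- enm_id: ZnO_NM110
  c: -0.61
  r_e: 0.35
  p_s: 0.52
  a: -1.34
  b: -2.42
  v: 3.05
- enm_id: SiO2_Amino
  c: -0.18
  r_e: 0.22
  p_s: 0.44
  a: -0.73
  b: -2.95
  v: 2.74
- enm_id: SiO2_Phosphat
  c: -0.45
  r_e: 0.31
  p_s: 0.58
  a: -1.05
  b: -2.70
  v: 2.91
- enm_id: Ag200_PVP
  c: -0.29
  r_e: 0.19
  p_s: 0.36
  a: -0.88
  b: -2.33
  v: 2.63
- enm_id: BaSO4_NM220
  c: -0.56
  r_e: 0.27
  p_s: 0.49
  a: -1.12
  b: -2.58
  v: 2.97
- enm_id: Ag50_Citrat
  c: -0.40
  r_e: 0.24
  p_s: 0.55
  a: -1.27
  b: -2.76
  v: 3.01
- enm_id: SiO2_Naked
  c: -0.37
  r_e: 0.30
  p_s: 0.62
  a: -1.18
  b: -2.89
  v: 3.09
- enm_id: ZrO2_Amino
  c: -0.23
  r_e: 0.21
  p_s: 0.41
  a: -0.81
  b: -2.49
  v: 2.69
- enm_id: ZrO2_TODacid
  c: -0.49
  r_e: 0.33
  p_s: 0.57
  a: -1.09
  b: -2.66
  v: 2.93
- enm_id: ZrO2_PEG
  c: -0.31
  r_e: 0.25
  p_s: 0.46
  a: -0.92
  b: -2.54
  v: 2.79
- enm_id: SiO2_PEG
  c: -0.26
  r_e: 0.20
  p_s: 0.39
  a: -0.79
  b: -2.45
  v: 2.66
- enm_id: sMWCNT
  c: 0.12
  r_e: 0.56
  p_s: -0.38
  a: -1.96
  b: -3.64
  v: 4.15
- enm_id: MWNT_OH
  c: 0.05
  r_e: 0.51
  p_s: -0.29
  a: -1.78
  b: -3.41
  v: 3.92
- enm_id: MWNT
  c: 0.18
  r_e: 0.60
  p_s: -0.44
  a: -2.08
  b: -3.80
  v: 4.31
- enm_id: MWNT_COOH_20nm
  c: 0.02
  r_e: 0.47
  p_s: -0.21
  a: -1.63
  b: -3.27
  v: 3.76
- enm_id: MWNT_COOH_50nm
  c: 0.08
  r_e: 0.53
  p_s: -0.33
  a: -1.85
  b: -3.52
  v: 4.03
- enm_id: FullrC60
  c: -1.10
  r_e: 0.74
  p_s: -0.87
  a: -2.63
  b: -4.45
  v: 5.27
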