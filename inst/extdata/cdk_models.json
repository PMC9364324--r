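{
  "comment": "Frozen descriptor-based QSAR equations for the 19 nanomaterials: log k = intercept + sum(coefficient * descriptor). r2_train / r2_validate are adjusted R2 for the 80/20 training/validation split; ad_fraction is the fraction of training+validation compounds inside the Williams-plot applicability domain.",
  "models": [
    {
      "enm_id": "Ag50_Citrat",
      "type": "metal",
      "intercept": 2.39,
      "terms": {"ALogP": 0.40, "Fsp3": -0.54, "khs.sOH": 0.37, "WTPT.4": -0.04, "ATSm1": -0.004},
      "r2_train": 0.82, "r2_validate": 0.83, "ad_fraction": 0.94
    },
    {
      "enm_id": "Ag200_PVP",
      "type": "metal",
      "intercept": 2.63,
      "terms": {"ALogP": 0.30, "khs.sOH": 0.32, "nAtom": -0.01, "Fsp3": -0.25, "nAcid": 0.22},
      "r2_train": 0.71, "r2_validate": 0.77, "ad_fraction": 0.93
    },
    {
      "enm_id": "AlOOH",
      "type": "metal",
      "intercept": 1.79,
      "terms": {"ALogP": 0.49, "nHBDon": 0.45, "Fsp3": -0.57, "ATSm1": 0.004, "nBase": -0.41},
      "r2_train": 0.83, "r2_validate": 0.84, "ad_fraction": 0.93
    },
    {
      "enm_id": "BaSO4_NM220",
      "type": "metal",
      "intercept": 1.73,
      "terms": {"ALogP": 0.30, "nAtomP": 0.03, "nHBDon": 0.23, "ATSm1": 0.004, "nSmallRings": 0.11},
      "r2_train": 0.86, "r2_validate": 0.86, "ad_fraction": 0.92
    },
    {
      "enm_id": "FullrC60",
      "type": "fullerene",
      "intercept": 0.15,
      "terms": {"ALogP": 0.79, "khs.aasC": -0.14, "khs.sssSiH": 1.53, "WPATH": -0.0001, "khs.aasN": -0.63},
      "r2_train": 0.91, "r2_validate": 0.90, "ad_fraction": 0.94
    },
    {
      "enm_id": "sMWCNT",
      "type": "carbon_nanotube",
      "intercept": 1.76,
      "terms": {"ATSp1": 0.003, "nAtomP": 0.09, "khs.ssssC": -0.39, "khs.sBr": 0.33, "khs.sOH": -0.13},
      "r2_train": 0.88, "r2_validate": 0.93, "ad_fraction": 0.93
    },
    {
      "enm_id": "MWNT_COOH_20nm",
      "type": "carbon_nanotube",
      "intercept": -0.81,
      "terms": {"AMR": 0.12, "Fsp3": -1.18, "ATSm4": 0.02, "MDEO.11": 0.53, "khs.aaaC": 0.17},
      "r2_train": 0.94, "r2_validate": 0.97, "ad_fraction": 0.93
    },
    {
      "enm_id": "MWNT_COOH_50nm",
      "type": "carbon_nanotube",
      "intercept": -0.005,
      "terms": {"AMR": 0.11, "nRotB": -0.15, "C1SP3": -0.14, "TopoPSA": 0.006, "khs.aaaC": 0.19},
      "r2_train": 0.97, "r2_validate": 0.98, "ad_fraction": 0.93
    },
    {
      "enm_id": "MWNT_OH",
      "type": "carbon_nanotube",
      "intercept": -0.35,
      "terms": {"ATSp1": 0.005, "nAtomP": 0.18, "khs.ssssC": -0.60, "khs.sBr": 0.60, "nHBDon": 0.23},
      "r2_train": 0.92, "r2_validate": 0.96, "ad_fraction": 0.94
    },
    {
      "enm_id": "MWNT",
      "type": "carbon_nanotube",
      "intercept": 1.53,
      "terms": {"ATSp1": 0.004, "khs.ssssC": -0.65, "nAtomP": 0.06, "MDEO.11": 0.44, "khs.sOH": -0.18},
      "r2_train": 0.91, "r2_validate": 0.94, "ad_fraction": 0.94
    },
    {
      "enm_id": "SiO2_Amino",
      "type": "metal",
      "intercept": 1.71,
      "terms": {"ALogP": 0.50, "nHBDon": 0.36, "nBase": -0.41, "nAcid": 0.31, "khs.sssSiH": -0.90},
      "r2_train": 0.85, "r2_validate": 0.87, "ad_fraction": 0.93
    },
    {
      "enm_id": "SiO2_Naked",
      "type": "metal",
      "intercept": 2.40,
      "terms": {"XLogP": 0.40, "Fsp3": -0.49, "khs.sOH": 0.35, "Kier2": -0.07, "khs.ssNH": -0.21},
      "r2_train": 0.80, "r2_validate": 0.82, "ad_fraction": 0.92
    },
    {
      "enm_id": "SiO2_PEG",
      "type": "metal",
      "intercept": 1.58,
      "terms": {"XLogP": 0.49, "fragC": -0.0004, "nHBDon": 0.41, "khs.ssssSi": -0.26, "nBase": -0.42},
      "r2_train": 0.77, "r2_validate": 0.77, "ad_fraction": 0.94
    },
    {
      "enm_id": "SiO2_Phosphat",
      "type": "metal",
      "intercept": 1.93,
      "terms": {"ALogP": 0.48, "nHBDon": 0.37, "Fsp3": -0.22, "nBase": -0.35, "nAcid": 0.30},
      "r2_train": 0.84, "r2_validate": 0.86, "ad_fraction": 0.93
    },
    {
      "enm_id": "TiO2_NM105",
      "type": "metal",
      "intercept": 1.96,
      "terms": {"ALogP": 0.40, "nHBDon": 0.36, "Fsp3": -0.52, "SCH.7": 0.41, "ATSm1": -0.004},
      "r2_train": 0.85, "r2_validate": 0.86, "ad_fraction": 0.93
    },
    {
      "enm_id": "ZnO_NM110",
      "type": "metal",
      "intercept": 1.62,
      "terms": {"ALogP": 0.54, "nHBDon": 0.41, "nBase": -0.41, "Fsp3": -0.32, "khs.sssSiH": 0.95},
      "r2_train": 0.86, "r2_validate": 0.87, "ad_fraction": 0.94
    },
    {
      "enm_id": "ZrO2_Amino",
      "type": "metal",
      "intercept": 1.71,
      "terms": {"ALogP": 0.53, "khs.sOH": 0.37, "ATSp5": -0.0002, "khs.sssSiH": 1.09, "nAcid": 0.30},
      "r2_train": 0.79, "r2_validate": 0.83, "ad_fraction": 0.94
    },
    {
      "enm_id": "ZrO2_PEG",
      "type": "metal",
      "intercept": 2.22,
      "terms": {"ALogP": 0.60, "khs.sOH": 0.45, "Kier1": -0.07, "Fsp3": 0.34, "khs.sssSiH": 1.14},
      "r2_train": 0.77, "r2_validate": 0.80, "ad_fraction": 0.95
    },
    {
      "enm_id": "ZrO2_TODacid",
      "type": "metal",
      "intercept": 1.61,
      "terms": {"XLogP": 0.46, "khs.sOH": 0.41, "ECCEN": -0.002, "khs.ssssSi": 0.22, "nAcid": -0.36},
      "r2_train": 0.74, "r2_validate": 0.79, "ad_fraction": 0.92
    }
  ]
}
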