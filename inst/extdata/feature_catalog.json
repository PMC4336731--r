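{
  "comment": "Catalogue of predictive variables. 'sets' lists the era-linked feature sets (C1/C2/C3 clinical, B1/B2/B3 in vitro diagnostic biomarker) each variable belongs to. Types drive encoding: continuous -> z-standardized, binary -> 0/1 passthrough, categorical -> one-hot with most frequent training level as reference.",
  "clinical": [
    {"name": "aha_lesion_class", "label": "AHA/ACC lesion class", "type": "categorical", "levels": ["A", "B1", "B2", "C"], "sets": ["C1", "C2", "C3"]},
    {"name": "angina", "label": "Angina", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "ccs_grade", "label": "Canadian Cardiovascular Society grading of angina pectoris", "type": "categorical", "levels": ["I", "II", "III", "IV"], "sets": ["C1", "C2", "C3"]},
    {"name": "angulation", "label": "Angulation", "type": "binary", "sets": ["C1", "C3"]},
    {"name": "bmi", "label": "Body mass index", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "hypercholesterolemia", "label": "Hypercholesterolemia", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "dissection", "label": "Dissection", "type": "binary", "sets": ["C1", "C3"]},
    {"name": "ejection_fraction", "label": "Ejection fraction", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "eccentric_lesion", "label": "Presence of eccentric lesion", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "family_history", "label": "Family history", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "history_bypass", "label": "History of bypass", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "history_intervention", "label": "History of intervention", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "history_mi", "label": "History of myocardial infarction", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "hypertension", "label": "Hypertension", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "lesion_length", "label": "Lesion length", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "lv_function", "label": "Left ventricular function", "type": "categorical", "levels": ["normal", "mild", "moderate", "severe"], "sets": ["C1", "C2"]},
    {"name": "min_lumen_diameter", "label": "Minimum lumen diameter (pre)", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "smoker", "label": "Smoker", "type": "binary", "sets": ["C1", "C2", "C3"]},
    {"name": "n_stents", "label": "Number of stents", "type": "continuous", "sets": ["C1", "C2"]},
    {"name": "nyha_class", "label": "New York Heart Association class", "type": "categorical", "levels": ["I", "II", "III", "IV"], "sets": ["C1", "C2", "C3"]},
    {"name": "height", "label": "Patient height", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "weight", "label": "Patient weight", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "plaques", "label": "Plaques", "type": "binary", "sets": ["C1", "C2"]},
    {"name": "reference_diameter", "label": "Reference diameter (pre)", "type": "continuous", "sets": ["C1", "C2", "C3"]},
    {"name": "st_elevation", "label": "ST elevation", "type": "binary", "sets": ["C2"]},
    {"name": "stenosis_type", "label": "Stenosis type", "type": "categorical", "levels": ["de_novo", "restenotic"], "sets": ["C1", "C2"]},
    {"name": "thrombus", "label": "Thrombus", "type": "binary", "sets": ["C1"]},
    {"name": "timi_rating", "label": "Thrombolysis in myocardial infarction (TIMI) rating", "type": "categorical", "levels": ["0", "1", "2", "3"], "sets": ["C1", "C2", "C3"]},
    {"name": "tortuosity", "label": "Tortuosity", "type": "binary", "sets": ["C1"]},
    {"name": "vessels_affected", "label": "Vessels affected", "type": "continuous", "sets": ["C1", "C2", "C3"]}
  ],
  "biomarker": [
    {"name": "cholesterol", "label": "Cholesterol", "type": "continuous", "sets": ["B1"]},
    {"name": "creatine_kinase", "label": "Creatine kinase (all isoforms)", "type": "continuous", "sets": ["B1", "B2"]},
    {"name": "ck_mb", "label": "Creatine kinase MB isoenzyme", "type": "continuous", "sets": ["B1", "B2"]},
    {"name": "creatinine", "label": "Creatinine", "type": "continuous", "sets": ["B2", "B3"]},
    {"name": "crp", "label": "C-reactive protein", "type": "continuous", "sets": ["B1", "B2", "B3"]},
    {"name": "hdl", "label": "High density lipoprotein", "type": "continuous", "sets": ["B1"]},
    {"name": "ldl", "label": "Low density lipoprotein", "type": "continuous", "sets": ["B1"]},
    {"name": "nt_probnp", "label": "N-terminal pro-brain natriuretic peptide", "type": "continuous", "sets": ["B3"]},
    {"name": "triglycerides", "label": "Triglycerides", "type": "continuous", "sets": ["B1"]},
    {"name": "troponin_t", "label": "Troponin T", "type": "continuous", "sets": ["B1", "B2", "B3"]},
    {"name": "hs_troponin_t", "label": "High-sensitivity troponin T", "type": "continuous", "sets": ["B3"]}
  ]
}
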