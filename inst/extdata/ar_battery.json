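{
  "metric": "percentage_points",
  "dead_band": 0.5,
  "conditions": {
    "Capacitation": {"inputs": {"HCO3_o": 1, "Ca_o": 1}},
    "NonCapacitating": {"inputs": {"HCO3_o": 0}},
    "Pg": {"inputs": {"Pg": 1}},
    "Ionomycin": {"inputs": {"A23187": 1}},
    "A23187": {"inputs": {"A23187": 1}},
    "DCCD": {"clamps": {"V_ATPase": 0}},
    "DIDS": {"clamps": {"SLC": 0}},
    "NNC": {"clamps": {"pH_a": 1}},
    "XC": {"clamps": {"IP3R_a": 0, "IP3R_ns": 0}},
    "TG": {"clamps": {"ACA": 0}},
    "cAMP": {"clamps": {"cAMP": 1}},
    "8-pCPT": {"clamps": {"EPAC": 1}},
    "Rab3A": {"clamps": {"Rab3A": 1}}
  },
  "notes": "Condition-to-node mapping: DCCD blocks the acrosomal V-ATPase; DIDS blocks the Cl-/HCO3- exchanger; NNC 55-0396 acts here as an acrosomal alkalinizing agent (weak-base accumulation), modeled as clamping pH_a alkaline; xestospongin C (XC) blocks both IP3 receptor pools; thapsigargin (TG) blocks the acrosomal Ca2+ ATPase; permeable cAMP analog and 8-pCPT clamp cAMP and EPAC active; Rab3A stands for loading active recombinant Rab3A. Each mapping is editable data; rows compare a condition arm against a baseline arm ('control' = the capacitated population as is).",
  "rows": [
    {"variable": "cAMP", "readout": "cAMP", "condition": ["Capacitation"],
     "baseline": ["NonCapacitating"], "reported": "up",
     "paper_model_delta": 2, "reference": "Visconti et al. 1995"},
    {"variable": "cAMP", "readout": "cAMP", "condition": ["Pg"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 3, "reference": "Sosa et al. 2016"},
    {"variable": "pH_a", "readout": "pH_a", "condition": ["Capacitation"],
     "baseline": ["NonCapacitating"], "reported": "up",
     "paper_model_delta": 3, "reference": "Nakanishi et al. 2001"},
    {"variable": "pH_a", "readout": "pH_a", "condition": ["DCCD"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 45, "reference": "Nakanishi et al. 2001"},
    {"variable": "pH_a", "readout": "pH_a", "condition": ["DIDS"],
     "baseline": "control", "reported": "down",
     "paper_model_delta": -1, "reference": "Nakanishi et al. 2001"},
    {"variable": "pH_a", "readout": "pH_a", "condition": ["NNC"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 45, "reference": "Chavez et al. 2018"},
    {"variable": "pH_a", "readout": "pH_a", "condition": ["NNC"],
     "baseline": ["Ionomycin"], "reported": "up",
     "paper_model_delta": 50, "reference": "Chavez et al. 2018"},
    {"variable": "pH_i", "readout": "pH_i", "condition": ["Capacitation"],
     "baseline": ["NonCapacitating"], "reported": "up",
     "paper_model_delta": 5, "reference": "Darszon et al.; Lishko et al."},
    {"variable": "Em", "readout": "Em", "condition": ["Capacitation"],
     "baseline": ["NonCapacitating"], "reported": "down",
     "paper_model_delta": -86, "reference": "Chavez et al. 2013"},
    {"variable": "Ca_i", "readout": "Ca_i", "condition": ["Capacitation"],
     "baseline": ["NonCapacitating"], "reported": "up",
     "paper_model_delta": 5, "reference": "Lishko et al.; Visconti et al."},
    {"variable": "Ca_i", "readout": "Ca_i", "condition": ["Pg"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 24, "reference": "Blackmore et al.; Kirkman-Brown et al."},
    {"variable": "Ca_i", "readout": "Ca_i", "condition": ["NNC"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 28, "reference": "Chavez et al. 2018"},
    {"variable": "Ca_i", "readout": "Ca_i", "condition": ["Ionomycin"],
     "baseline": ["NNC"], "reported": "up",
     "paper_model_delta": 20, "reference": "Chavez et al. 2018"},
    {"variable": "Ca_a", "readout": "Ca_a", "condition": ["Pg"],
     "baseline": "control", "reported": "down",
     "paper_model_delta": -9, "reference": "Rossato et al.; De Blas et al."},
    {"variable": "Swelling", "readout": "Swell", "condition": ["Capacitation"],
     "baseline": ["NonCapacitating"], "reported": "up",
     "paper_model_delta": 30, "reference": "Sosa et al. 2016"},
    {"variable": "Swelling", "readout": "Swell", "condition": ["XC", "A23187"],
     "baseline": ["XC"], "reported": "up",
     "paper_model_delta": 61, "reference": "Sosa et al. 2016"},
    {"variable": "Swelling", "readout": "Swell", "condition": ["XC", "TG"],
     "baseline": ["XC"], "reported": "up",
     "paper_model_delta": 61, "reference": "Sosa et al. 2016"},
    {"variable": "Swelling", "readout": "Swell", "condition": ["XC", "cAMP"],
     "baseline": ["XC"], "reported": "up",
     "paper_model_delta": 70, "reference": "Sosa et al. 2016"},
    {"variable": "Swelling", "readout": "Swell", "condition": ["XC", "8-pCPT"],
     "baseline": ["XC"], "reported": "up",
     "paper_model_delta": 70, "reference": "Sosa et al. 2016"},
    {"variable": "Swelling", "readout": "Swell", "condition": ["XC", "Rab3A"],
     "baseline": ["XC"], "reported": "up",
     "paper_model_delta": 70, "reference": "Sosa et al. 2016"},
    {"variable": "Swelling", "readout": "Swell", "condition": ["XC", "Pg"],
     "baseline": ["XC"], "reported": "up", "known_discrepancy": true,
     "paper_model_delta": -3, "reference": "Sosa et al. 2016"},
    {"variable": "AR", "readout": "Fusion", "condition": ["DCCD"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 55, "reference": "Nakanishi et al. 2001"},
    {"variable": "AR", "readout": "Fusion", "condition": ["DIDS"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 7, "reference": "Nakanishi et al. 2001"},
    {"variable": "AR", "readout": "Fusion", "condition": ["Ionomycin"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 28, "reference": "Chavez et al. 2018"},
    {"variable": "AR", "readout": "Fusion", "condition": ["NNC"],
     "baseline": "control", "reported": "up",
     "paper_model_delta": 85, "reference": "Chavez et al. 2018"},
    {"variable": "AR", "readout": "Fusion", "condition": ["NNC"],
     "baseline": ["Ionomycin"], "reported": "up",
     "paper_model_delta": 57, "reference": "Chavez et al. 2018"}
  ]
}
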