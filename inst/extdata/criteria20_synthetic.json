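[
  {"tool": "SIFT",           "kind": "numeric_below", "threshold": 0.05,  "weight": 2},
  {"tool": "PolyPhen2",      "kind": "numeric_above", "threshold": 0.8,   "weight": 2},
  {"tool": "CADD_phred",     "kind": "numeric_above", "threshold": 20,    "weight": 1},
  {"tool": "CADD_raw",       "kind": "numeric_above", "threshold": 2,     "weight": 1},
  {"tool": "GERP++RS",       "kind": "numeric_above", "threshold": 4,     "weight": 2},
  {"tool": "M-CAP",          "kind": "numeric_above", "threshold": 0.025, "weight": 2},
  {"tool": "LoFtool",        "kind": "numeric_below", "threshold": 0.5,   "weight": 1},
  {"tool": "Condel",         "kind": "label_in", "damaging_labels": ["deleterious"], "weight": 1},
  {"tool": "DANN",           "kind": "label_in", "damaging_labels": ["D"],           "weight": 1},
  {"tool": "FATHMM",         "kind": "label_in", "damaging_labels": ["D"],           "weight": 1},
  {"tool": "LRT",            "kind": "label_in", "damaging_labels": ["D"],           "weight": 1},
  {"tool": "MetaLR",         "kind": "label_in", "damaging_labels": ["D"],           "weight": 1},
  {"tool": "MutationTaster", "kind": "label_in", "damaging_labels": ["A", "D"],      "weight": 2},
  {"tool": "PROVEAN",        "kind": "label_in", "damaging_labels": ["D"],           "weight": 2}
]
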