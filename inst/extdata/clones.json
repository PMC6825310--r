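[
  {
    "Name": "healthy",
    "Description": "unmutated mammary cell, physiological Wnt and normoxia",
    "Perturbations": []
  },
  {
    "Name": "myc_low",
    "Description": "Wnt-driven Myc-low clone, pure tumor: hypoxic, Wnt-rich",
    "Perturbations": {
      "Wnt1_env": 4,
      "Hypoxia": 1
    }
  },
  {
    "Name": "myc_low_mixed",
    "Description": "Myc-low clone in a biclonal tumor: Wnt-rich, normoxic",
    "Perturbations": {
      "Wnt1_env": 4
    }
  },
  {
    "Name": "myc_high_pure",
    "Description": "Myc forced to maximum, pure tumor: paracrine Wnt source lost",
    "Perturbations": {
      "Myc": 4,
      "Wnt1_env": 0
    }
  },
  {
    "Name": "myc_high_mixed",
    "Description": "Myc forced to maximum with paracrine Wnt1 from Myc-low neighbors",
    "Perturbations": {
      "Myc": 4,
      "Wnt1_env": 4
    }
  }
]
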