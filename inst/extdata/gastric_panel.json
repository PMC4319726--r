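[
  {
    "id": "rs2294008",
    "gene": "PSCA",
    "alleles": "C>T",
    "reference_genotype": "CC",
    "risk_genotypes": ["CT", "TT"],
    "direction": "risk"
  },
  {
    "id": "rs2976392",
    "gene": "PSCA",
    "alleles": "G>A",
    "reference_genotype": "GG",
    "risk_genotypes": ["AG", "AA"],
    "direction": "risk"
  },
  {
    "id": "rs2274223",
    "gene": "PLCE1",
    "alleles": "A>G",
    "reference_genotype": "AA",
    "risk_genotypes": ["AG", "GG"],
    "direction": "risk"
  },
  {
    "id": "rs4072037",
    "gene": "MUC1",
    "alleles": "T>C",
    "reference_genotype": "TT",
    "risk_genotypes": "TT",
    "direction": "protective"
  }
]
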