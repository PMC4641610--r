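{
  "panel": [
    {"name": "RT-18S-F2", "sequence": "ACCGCCCTAGTTCTAACCGTAAA", "role": "forward_primer"},
    {"name": "RT-18S-R2", "sequence": "CCGCCGAGCCATTGTAGTAA", "role": "reverse_primer"},
    {"name": "RT-18S-P2", "sequence": "TGTCATCTAGCGATCCGCCGA", "role": "probe", "fluorophore": "CAL Fluor Red 610", "quencher": "BHQ-2"},
    {"name": "ITSF", "sequence": "TTGAACATCGACATTTCGAACGCAC", "role": "forward_primer"},
    {"name": "ITSR", "sequence": "TCCTCCGCTTATTGATATGC", "role": "reverse_primer"},
    {"name": "425F", "sequence": "ACAAYACCAGAGGGGGTYGC", "role": "forward_primer"},
    {"name": "568R", "sequence": "CGTCGATGCGCTCTTCGG", "role": "reverse_primer"},
    {"name": "QP-Harm-ITS2-P8", "sequence": "TGTCGTCCGYTTTAGCGTGAGAC", "role": "probe", "fluorophore": "FAM", "quencher": "BHQ-1"},
    {"name": "RT-ITS-zea", "sequence": "CAACGCCATTAGTAGGCGGACTC", "role": "probe", "fluorophore": "TET", "quencher": "BHQ-1"}
  ],
  "channel_roles": {
    "CAL Fluor Red 610": "control",
    "FAM": "armigera_target",
    "TET": "zea_target"
  },
  "pairs": [
    {"name": "18S", "forward": "RT-18S-F2", "reverse": "RT-18S-R2", "probes": ["RT-18S-P2"]},
    {"name": "ITS2", "forward": "425F", "reverse": "568R", "probes": ["QP-Harm-ITS2-P8", "RT-ITS-zea"]}
  ],
  "caller": {"rfu_threshold": 30.0, "baseline_window": [3, 15], "max_cycles": 40},
  "rules": {"max_cq": 40, "delta_min": 0, "delta_max": 7},
  "protocol_metadata": {
    "cycling": "62C annealing, 40 cycles; default growth-curve threshold 30 fluorescence units",
    "instrument": "SmartCycler-class platform; fluorophores swapped for channel compatibility"
  }
}
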