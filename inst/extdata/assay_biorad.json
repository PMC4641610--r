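{
  "panel": [
    {"name": "RT-18S-F2", "sequence": "ACCGCCCTAGTTCTAACCGTAAA", "role": "forward_primer"},
    {"name": "RT-18S-R2", "sequence": "CCGCCGAGCCATTGTAGTAA", "role": "reverse_primer"},
    {"name": "RT-18S-P2", "sequence": "TGTCATCTAGCGATCCGCCGA", "role": "probe", "fluorophore": "Quasar 670", "quencher": "BHQ-2"},
    {"name": "ITSF", "sequence": "TTGAACATCGACATTTCGAACGCAC", "role": "forward_primer"},
    {"name": "ITSR", "sequence": "TCCTCCGCTTATTGATATGC", "role": "reverse_primer"},
    {"name": "425F", "sequence": "ACAAYACCAGAGGGGGTYGC", "role": "forward_primer"},
    {"name": "568R", "sequence": "CGTCGATGCGCTCTTCGG", "role": "reverse_primer"},
    {"name": "QP-Harm-ITS2-P8", "sequence": "TGTCGTCCGYTTTAGCGTGAGAC", "role": "probe", "fluorophore": "FAM", "quencher": "BHQ-1"},
    {"name": "RT-ITS-zea", "sequence": "CAACGCCATTAGTAGGCGGACTC", "role": "probe", "fluorophore": "HEX", "quencher": "BHQ-1"}
  ],
  "channel_roles": {
    "Quasar 670": "control",
    "FAM": "armigera_target",
    "HEX": "zea_target"
  },
  "pairs": [
    {"name": "18S", "forward": "RT-18S-F2", "reverse": "RT-18S-R2", "probes": ["RT-18S-P2"]},
    {"name": "ITS2", "forward": "425F", "reverse": "568R", "probes": ["QP-Harm-ITS2-P8", "RT-ITS-zea"]},
    {"name": "ITS2_sequencing", "forward": "ITSF", "reverse": "ITSR", "probes": []}
  ],
  "caller": {"rfu_threshold": 1000.0, "baseline_window": [3, 15], "max_cycles": 40},
  "rules": {"max_cq": 40, "delta_min": 0, "delta_max": 7},
  "protocol_metadata": {
    "reaction_volume_ul": 20,
    "primer_final_uM": 0.5,
    "its2_probe_final_uM": 0.2,
    "control_probe_final_uM": 0.4,
    "cycling": "95C 7:30; 40x (95C 0:10, 62C 0:20); 40C 0:10; plate read at end of each 62C step",
    "instrument": "96-well real-time PCR system, single threshold, baseline subtracted"
  }
}
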