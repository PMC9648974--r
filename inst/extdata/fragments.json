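{
  "glucose": {
    "comment": "glucose methoxime-penta-TBDMS [M-57]+ fragment",
    "element_counts": {"C": 33, "H": 76, "N": 1, "O": 6, "Si": 5},
    "n_labelable": 6
  },
  "lactate": {
    "comment": "lactate di-TBDMS [M-57]+ fragment",
    "element_counts": {"C": 11, "H": 25, "O": 3, "Si": 2},
    "n_labelable": 3
  }
}
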