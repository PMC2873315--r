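{
  "name": "Dictyostelium model 1 (ligand-driven inhibitor)",
  "states": ["A", "I", "Rstar"],
  "params": {
    "kr": 1,
    "kmr": 1,
    "ka": 3,
    "kma": 2,
    "ki": 1,
    "kmi": 0.1,
    "RT": 0.766666666666667
  },
  "drift": ["-kma*A", "-kmi*I", "kr*A*(RT - Rstar) - kmr*I*Rstar"],
  "input_map": [
    "ka",
    "ki",
    "0"
  ],
  "output_map": ["A", "I", "Rstar"],
  "basal_input": 0.2
}
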