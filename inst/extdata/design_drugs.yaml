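control: Control
populations:
- name: Control
  n_cells: 150
  cv: 0.35
  mean_abundance:
    HER2: 150.0
    CD44: 40.0
    EGFR: 70.0
    CD55: 60.0
    MUC1: 90.0
    EpCAM: 110.0
    Nucleolin: 80.0
    Endo40: 70.0
    Endo70: 55.0
    Endo120: 45.0
    EdU: 35.0
    ODYA: 50.0
    AltQ2: 40.0
    Amide13C: 120.0
    Amide12C: 250.0
    PS: 35.0
- name: CytoD
  n_cells: 150
  cv: 0.35
  fold_change:
    Endo40: 0.55
    Endo70: 0.6
    Endo120: 0.5
    PS: 0.6
- name: CHX
  n_cells: 150
  cv: 0.35
  fold_change:
    Amide13C: 0.3
    EdU: 0.8
    ODYA: 0.85
- name: Trastuzumab
  n_cells: 150
  cv: 0.35
  fold_change:
    HER2: 0.5
    EdU: 0.8
- name: Cisplatin
  n_cells: 150
  cv: 0.35
  fold_change:
    EdU: 0.3
    Amide13C: 0.8
    Nucleolin: 0.85
- name: H2O2
  n_cells: 150
  cv: 0.35
  fold_change:
    AltQ2: 0.55
    ODYA: 0.75
    EdU: 0.7
    Amide13C: 0.8
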