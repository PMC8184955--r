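control: Control
populations:
- name: Control
  n_cells: 150
  cv: 0.35
  mean_abundance:
    Endo40: 100.0
    Endo70: 80.0
    Endo120: 60.0
    PS: 30.0
    Amide12C: 250.0
- name: CPZ
  n_cells: 150
  cv: 0.35
  fold_change:
    Endo40: 0.45
    Endo70: 0.5
    Endo120: 0.4
- name: Nystatin
  n_cells: 150
  cv: 0.35
  fold_change:
    Endo40: 1.1
    Endo70: 0.55
    Endo120: 0.4
- name: Cold4C
  n_cells: 150
  cv: 0.35
  fold_change:
    Endo40: 0.25
    Endo70: 0.25
    Endo120: 0.2
- name: CytoD_6h
  n_cells: 150
  cv: 0.35
  fold_change:
    Endo40: 0.55
    Endo70: 0.6
    Endo120: 0.5
- name: CytoD_60h
  n_cells: 150
  cv: 0.35
  fold_change:
    Endo40: 1.6
    Endo70: 1.8
    Endo120: 1.7
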