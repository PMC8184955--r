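grid_step: 1.0
components:
- name: Amide12C
  window: amide
  role: auxiliary
  peaks:
  - center: 1574.0
    fwhm: 15.0
    amplitude: 1.0
  - center: 1659.0
    fwhm: 15.0
    amplitude: 1.5
- name: Amide13C
  window: amide
  role: probe
  peaks:
  - center: 1534.0
    fwhm: 15.0
    amplitude: 1.0
  - center: 1619.0
    fwhm: 15.0
    amplitude: 1.5
- name: PS
  window: amide
  role: auxiliary
  peaks:
  - center: 1602.0
    fwhm: 15.0
    amplitude: 1.0
- name: AltQ2
  window: silent
  role: probe
  peaks:
  - center: 2290.0
    fwhm: 15.0
    amplitude: 1.0
- name: CD44
  window: silent
  role: probe
  peaks:
  - center: 2079.0
    fwhm: 15.0
    amplitude: 1.0
- name: CD55
  window: silent
  role: probe
  peaks:
  - center: 2153.0
    fwhm: 15.0
    amplitude: 1.0
- name: EGFR
  window: silent
  role: probe
  peaks:
  - center: 2133.0
    fwhm: 15.0
    amplitude: 1.0
- name: EdU
  window: silent
  role: probe
  peaks:
  - center: 2065.0
    fwhm: 15.0
    amplitude: 1.0
- name: Endo120
  window: silent
  role: probe
  peaks:
  - center: 2092.0
    fwhm: 15.0
    amplitude: 1.0
- name: Endo40
  window: silent
  role: probe
  peaks:
  - center: 2207.0
    fwhm: 15.0
    amplitude: 1.0
- name: Endo70
  window: silent
  role: probe
  peaks:
  - center: 2118.0
    fwhm: 15.0
    amplitude: 1.0
- name: EpCAM
  window: silent
  role: probe
  peaks:
  - center: 2194.0
    fwhm: 15.0
    amplitude: 1.0
- name: HER2
  window: silent
  role: probe
  peaks:
  - center: 2052.0
    fwhm: 15.0
    amplitude: 1.0
- name: MUC1
  window: silent
  role: probe
  peaks:
  - center: 2175.0
    fwhm: 15.0
    amplitude: 1.0
- name: Nucleolin
  window: silent
  role: probe
  peaks:
  - center: 2218.0
    fwhm: 15.0
    amplitude: 1.0
- name: ODYA
  window: silent
  role: probe
  peaks:
  - center: 2250.0
    fwhm: 15.0
    amplitude: 1.0
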