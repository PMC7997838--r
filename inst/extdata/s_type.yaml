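compounds:
- name: syringamide
  class: S
  measurable: yes
  initial_umol_per_l: 32.6
- name: syringaldehyde
  class: S
  measurable: yes
  initial_umol_per_l: 5.8
- name: syringic acid
  class: S
  measurable: yes
  initial_umol_per_l: 6.9
reactions:
- substrate: syringamide
  product: syringic acid
  law: first_order
  k: 0.0001
- substrate: syringaldehyde
  product: syringic acid
  law: first_order
  k: 0.0001
- substrate: syringic acid
  law: first_order
  k: 0.0001
free_parameters:
- substrate: syringamide
  param: k
- substrate: syringaldehyde
  param: k
- substrate: syringic acid
  param: k
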