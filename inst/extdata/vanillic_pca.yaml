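compounds:
- name: vanillic acid
  class: G
  measurable: yes
  initial_umol_per_l: 27.0
- name: protocatechuic acid
  class: other
  measurable: yes
  initial_umol_per_l: 6.0
reactions:
- substrate: vanillic acid
  product: protocatechuic acid
  law: first_order
  k: 0.0001
- substrate: protocatechuic acid
  law: first_order
  k: 0.0001
free_parameters:
- substrate: vanillic acid
  param: k
- substrate: protocatechuic acid
  param: k
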