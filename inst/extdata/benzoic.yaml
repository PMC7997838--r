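compounds:
- name: benzoic acid
  class: other
  measurable: yes
  initial_umol_per_l: 160.0
reactions:
- substrate: benzoic acid
  law: first_order
  k: 0.0001
free_parameters:
- substrate: benzoic acid
  param: k
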