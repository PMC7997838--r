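compounds:
- name: p-coumaroyl amide
  class: H
  measurable: yes
  initial_umol_per_l: 2090.0
- name: p-coumaric acid
  class: H
  measurable: yes
  initial_umol_per_l: 446.0
- name: p-coumaroyl-CoA
  class: H
  measurable: no
  initial_umol_per_l: 0.0
- name: p-hydroxybenzaldehyde
  class: H
  measurable: yes
  initial_umol_per_l: 59.4
- name: p-hydroxybenzamide
  class: H
  measurable: yes
  initial_umol_per_l: 20.6
- name: p-hydroxybenzoic acid
  class: H
  measurable: yes
  initial_umol_per_l: 47.8
- name: feruloyl amide
  class: G
  measurable: yes
  initial_umol_per_l: 1040.0
- name: ferulic acid
  class: G
  measurable: yes
  initial_umol_per_l: 20.9
- name: feruloyl-CoA
  class: G
  measurable: no
  initial_umol_per_l: 0.0
- name: vanillin
  class: G
  measurable: yes
  initial_umol_per_l: 43.3
- name: vanillamide
  class: G
  measurable: yes
  initial_umol_per_l: 60.5
- name: vanillic acid
  class: G
  measurable: yes
  initial_umol_per_l: 27.0
reactions:
- substrate: p-coumaroyl amide
  product: p-coumaric acid
  law: first_order
  k: 0.0001
- substrate: p-coumaric acid
  product: p-coumaroyl-CoA
  law: first_order
  k: 0.0001
- substrate: p-coumaroyl-CoA
  product: p-hydroxybenzaldehyde
  law: first_order
  k: 0.0001
- substrate: p-hydroxybenzaldehyde
  product: p-hydroxybenzoic acid
  law: first_order
  k: 0.0001
- substrate: p-hydroxybenzamide
  product: p-hydroxybenzoic acid
  law: first_order
  k: 0.0001
- substrate: p-hydroxybenzoic acid
  law: first_order
  k: 0.0001
- substrate: feruloyl amide
  product: ferulic acid
  law: first_order
  k: 0.0001
- substrate: ferulic acid
  product: feruloyl-CoA
  law: first_order
  k: 0.0001
- substrate: feruloyl-CoA
  product: vanillin
  law: first_order
  k: 0.0001
- substrate: vanillin
  product: vanillic acid
  law: first_order
  k: 0.0001
- substrate: vanillamide
  product: vanillic acid
  law: first_order
  k: 0.0001
- substrate: vanillic acid
  law: first_order
  k: 0.0001
free_parameters:
- substrate: p-coumaroyl amide
  param: k
- substrate: p-coumaric acid
  param: k
- substrate: p-coumaroyl-CoA
  param: k
- substrate: p-hydroxybenzaldehyde
  param: k
- substrate: p-hydroxybenzamide
  param: k
- substrate: p-hydroxybenzoic acid
  param: k
- substrate: feruloyl amide
  param: k
- substrate: ferulic acid
  param: k
- substrate: feruloyl-CoA
  param: k
- substrate: vanillin
  param: k
- substrate: vanillamide
  param: k
- substrate: vanillic acid
  param: k
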