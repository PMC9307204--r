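system: vhuman
compound: vC2
fraction_unbound: 0.05
dose_total: 100000
standard_fraction: 0.5
n_ts: 21600
n_mc: 12
base_seed: 1
dosing_mode: first_order
flow:
  k_absorption: 0.002
  f_body_to_pv: 0.03
  f_media_to_interface: 0.03
  ss_flow_rate: 0.8
  forward_bias: 0.2
  lateral_bias: 0.3
  core_split: 0.5
  lateral_hop_guard: 10
structure:
  layer_sizes:
  - 45
  - 25
  - 20
  - 15
  - 9
  inter_layer_edges:
  - 55
  - 65
  - 35
  - 25
  intra_layer_edges:
  - 20
  - 7
  - 5
  - 2
  - 0
  width: 15
  length_probs:
    '3': 0.014
    '4': 0.378
    '5': 0.354
    '6': 0.15
    '7': 0.1
    '8': 0.004
  culture_units: 114
  culture_length: 5
  enzymes_min: 5
  enzymes_max: 10
  open_fraction: 0.01
bands:
  pp_max_dPV: 5.0
  pc_max_dCV: 5.0
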