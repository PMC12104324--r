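graph:
  lnls: [I, II, III, IV, V, VII]
  tumor_arcs: [I, II, III, IV, V, VII]
  lnl_arcs:
    - [I, II]
    - [II, III]
    - [III, IV]
    - [IV, V]
t_max: 10
p_early: 0.3
modalities:
  imaging: {sensitivity: 0.81, specificity: 0.76}
  FNA: {sensitivity: 0.80, specificity: 0.98}
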