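# advanced tumor crossing the midline, extensive ipsilateral involvement,
# contralateral level II positive and confirmed by fine needle aspiration
t_group: advanced
midline_extension: true
ipsi_involved: [II, III, IV]
contra_involved: [II]
fna_contra: [II]
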