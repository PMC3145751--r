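# Synthetic example clade hypotheses for the alignment/trees in this folder.
- name: cladeA
  category: higher-level
  members: [t01, t02, t03]
- name: cladeB
  category: morphogroup
  members: [t05, t06]
- name: undersampled
  category: proposed
  members: [t07, not_in_data]
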