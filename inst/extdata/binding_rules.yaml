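# Binding-capability rule table: rules fire in order, first match wins.
# Omitted positions match any residue.
- name: S9_V14_DRE
  pos9: [S]
  pos14: [V, I]
  category: DRE_preferring
- name: NQKTI9_V14_S15_DRE
  pos9: [N, Q, K, T, I]
  pos14: [V, I]
  pos15: [S]
  category: DRE_preferring
- name: NQKTID9_V14_both
  pos9: [N, Q, K, T, I, D]
  pos14: [V, I]
  category: both_capable
- name: H9_GCC
  pos9: [H]
  category: GCC_preferring
- name: P9_A14_A15_GCC_strong
  pos9: [P]
  pos14: [A]
  pos15: [A]
  category: both_capable
- name: P9_both
  pos9: [P]
  category: both_capable
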