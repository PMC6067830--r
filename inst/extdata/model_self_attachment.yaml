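model: self_attachment
current_gain: 0.035
heterogeneous: yes
regions:
- name: BLMA_neg
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
  valence: negative
- name: BLMA_pos
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
  valence: positive
- name: BLMA_i
  n_exc: 0.0
  n_inh: 100.0
  type_inh: FS
  valence: interneuron
- name: AI
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
- name: PI
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
- name: aMCC
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
- name: mPFC
  n_exc: 1000.0
  n_inh: 250.0
  type_exc: RS
  type_inh: FS
- name: mPOA
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
- name: VTA
  n_exc: 100.0
  n_inh: 0.0
  type_exc: IB
  da: yes
- name: NAc
  n_exc: 0.0
  n_inh: 200.0
  type_inh: RS
- name: VP
  n_exc: 0.0
  n_inh: 200.0
  type_inh: FS
- name: mOFC
  n_exc: 200.0
  n_inh: 50.0
  type_exc: RS
  type_inh: FS
gradient:
  close:
    r: 7.0
    p: 0.0025
  distant:
    r: 14.0
    p: 0.035
  orientation: ventral_at_high_index
projections:
- source: AI
  source_pop: exc
  target: AI
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 10.0
  delay_max: 10.0
- source: AI
  source_pop: inh
  target: AI
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 8.0
  delay_max: 10.0
- source: AI
  source_pop: inh
  target: AI
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: PI
  source_pop: exc
  target: PI
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 13.0
  delay_max: 10.0
- source: PI
  source_pop: inh
  target: PI
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 6.0
  delay_max: 10.0
- source: PI
  source_pop: inh
  target: PI
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: aMCC
  source_pop: exc
  target: aMCC
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 8.0
  delay_max: 10.0
- source: aMCC
  source_pop: inh
  target: aMCC
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 10.0
  delay_max: 10.0
- source: aMCC
  source_pop: inh
  target: aMCC
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: mPFC
  source_pop: exc
  target: mPFC
  target_pop: inh
  sign: excitatory
  probability: 0.04
  weight: 7.0
  delay_max: 10.0
- source: mPFC
  source_pop: inh
  target: mPFC
  target_pop: exc
  sign: inhibitory
  probability: 0.08
  weight: 1.875
  delay_max: 10.0
- source: mPFC
  source_pop: inh
  target: mPFC
  target_pop: inh
  sign: inhibitory
  probability: 0.06
  weight: 5.0
  delay_max: 10.0
- source: BLMA_neg
  source_pop: exc
  target: BLMA_neg
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 10.0
  delay_max: 10.0
- source: BLMA_neg
  source_pop: inh
  target: BLMA_neg
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 8.0
  delay_max: 10.0
- source: BLMA_neg
  source_pop: inh
  target: BLMA_neg
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: BLMA_pos
  source_pop: exc
  target: BLMA_pos
  target_pop: exc
  sign: excitatory
  probability: 0.1
  weight: 12.8
  delay_max: 10.0
- source: BLMA_pos
  source_pop: exc
  target: BLMA_pos
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 13.0
  delay_max: 10.0
- source: BLMA_pos
  source_pop: inh
  target: BLMA_pos
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 6.0
  delay_max: 10.0
- source: BLMA_pos
  source_pop: inh
  target: BLMA_pos
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: mPOA
  source_pop: exc
  target: mPOA
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 10.0
  delay_max: 10.0
- source: mPOA
  source_pop: inh
  target: mPOA
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 6.0
  delay_max: 10.0
- source: mPOA
  source_pop: inh
  target: mPOA
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: VP
  source_pop: inh
  target: VP
  target_pop: inh
  sign: inhibitory
  probability: 0.6
  weight: 30.0
  delay_max: 10.0
- source: BLMA_neg
  source_pop: exc
  target: AI
  target_pop: exc
  sign: excitatory
  probability: 0.1
  weight: 3.2
  delay_max: 10.0
- source: AI
  source_pop: exc
  target: aMCC
  target_pop: exc
  sign: excitatory
  probability: 0.1
  weight: 7.5
  delay_max: 10.0
- source: aMCC
  source_pop: exc
  target: AI
  target_pop: exc
  sign: excitatory
  probability: 0.1
  weight: 3.2
  delay_max: 10.0
- source: AI
  source_pop: exc
  target: mPFC
  target_pop: exc
  sign: excitatory
  probability: 0.05
  weight: 1.5625
  delay_max: 10.0
- source: mPFC
  source_pop: exc
  target: mPOA
  target_pop: exc
  sign: excitatory
  probability: 0.04
  weight: 25.0
  delay_max: 10.0
  sampling: mpfc_gradient
  gradient: close
- source: mPFC
  source_pop: exc
  target: BLMA_pos
  target_pop: exc
  sign: excitatory
  probability: 0.04
  weight: 10.0
  delay_max: 10.0
  sampling: mpfc_gradient
  gradient: close
- source: mPOA
  source_pop: exc
  target: VTA
  target_pop: da
  sign: excitatory
  probability: 0.1
  weight: 15.0
  delay_max: 10.0
- source: VTA
  source_pop: da
  target: NAc
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: NAc
  source_pop: inh
  target: VP
  target_pop: inh
  sign: inhibitory
  probability: 0.5
  weight: 42.0
  delay_max: 10.0
- source: BLMA_pos
  source_pop: exc
  target: NAc
  target_pop: inh
  sign: excitatory
  probability: 0.1
  weight: 40.0
  delay_max: 10.0
- source: BLMA_pos
  source_pop: exc
  target: VP
  target_pop: inh
  sign: excitatory
  probability: 0.1
  weight: 31.5
  delay_max: 10.0
- source: BLMA_pos
  source_pop: exc
  target: BLMA_i
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 1.0
  delay_max: 10.0
- source: BLMA_i
  source_pop: inh
  target: BLMA_neg
  target_pop: exc
  sign: inhibitory
  probability: 1.0
  weight: 0.85
  delay_max: 10.0
- source: mOFC
  source_pop: exc
  target: mOFC
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 12.0
  delay_max: 10.0
- source: mOFC
  source_pop: inh
  target: mOFC
  target_pop: exc
  sign: inhibitory
  probability: 0.4
  weight: 3.0
  delay_max: 10.0
- source: mOFC
  source_pop: inh
  target: mOFC
  target_pop: inh
  sign: inhibitory
  probability: 0.3
  weight: 5.0
  delay_max: 10.0
- source: mOFC
  source_pop: exc
  target: AI
  target_pop: exc
  sign: excitatory
  probability: 0.1
  weight: 4.6875
  delay_max: 10.0
- source: mOFC
  source_pop: exc
  target: BLMA_i
  target_pop: inh
  sign: excitatory
  probability: 0.2
  weight: 9.0
  delay_max: 10.0
- source: mOFC
  source_pop: exc
  target: BLMA_pos
  target_pop: exc
  sign: excitatory
  probability: 0.1
  weight: 13.0
  delay_max: 10.0
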