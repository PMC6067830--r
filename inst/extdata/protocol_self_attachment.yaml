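model: self_attachment
levels:
  L: 0.05
  M: 0.1
  H: 0.15
amplitude: 90.0
perturb_fraction: 0.1
phase_len: 10000
rules:
- region: BLMA_neg
  phase: 1.0
  rule: band
  p1: 0.1
  p2: 0.15
- region: BLMA_neg
  phase: 2.0
  rule: band
  p1: 0.1
  p2: 0.15
- region: BLMA_neg
  phase: 3.0
  rule: band
  p1: 0.1
  p2: 0.15
- region: AI
  phase: 1.0
  rule: band
  p1: 0.1
  p2: 0.15
- region: AI
  phase: 2.0
  rule: ramp
  p1: 0.15
  p2: 0.05
- region: AI
  phase: 3.0
  rule: band
  p1: 0.05
  p2: 0.1
- region: PI
  phase: 1.0
  rule: band
  p1: 0.1
  p2: 0.15
- region: PI
  phase: 2.0
  rule: ramp
  p1: 0.15
  p2: 0.05
- region: PI
  phase: 3.0
  rule: band
  p1: 0.05
  p2: 0.1
- region: aMCC
  phase: 1.0
  rule: band
  p1: 0.05
  p2: 0.1
- region: aMCC
  phase: 2.0
  rule: ramp
  p1: 0.05
  p2: 0.15
- region: aMCC
  phase: 3.0
  rule: band
  p1: 0.1
  p2: 0.15
- region: mPFC
  phase: 1.0
  rule: band
  p1: 0.05
  p2: 0.1
  mode: close
- region: mPFC
  phase: 2.0
  rule: ramp
  p1: 0.05
  p2: 0.15
  mode: close
- region: mPFC
  phase: 3.0
  rule: band
  p1: 0.1
  p2: 0.15
  mode: close
- region: mOFC
  phase: 1.0
  rule: band
  p1: 0.05
  p2: 0.1
- region: mOFC
  phase: 2.0
  rule: band
  p1: 0.05
  p2: 0.1
- region: mOFC
  phase: 3.0
  rule: ramp
  p1: 0.05
  p2: 0.15
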