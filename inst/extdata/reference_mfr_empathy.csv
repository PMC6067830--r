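region,subpop,time_ms,mfr_hz
AI,exc,10000,1.08
AI,inh,10000,8.80
AI,exc,20000,0.22
AI,inh,20000,1.92
AI,exc,30000,0.45
AI,inh,30000,4.33
PI,exc,10000,1.09
PI,inh,10000,10.55
PI,exc,20000,0.06
PI,inh,20000,1.97
PI,exc,30000,0.34
PI,inh,30000,3.69
aMCC,exc,10000,1.09
aMCC,inh,10000,5.97
aMCC,exc,20000,0.93
aMCC,inh,20000,4.79
aMCC,exc,30000,1.05
aMCC,inh,30000,5.61
mPFC,exc,10000,0.84
mPFC,inh,10000,5.25
mPFC,exc,20000,1.30
mPFC,inh,20000,8.53
mPFC,exc,30000,1.26
mPFC,inh,30000,8.82
BLMA_neg,exc,10000,0.92
BLMA_neg,exc,20000,0.75
BLMA_neg,exc,30000,0.72
BLMA_pos,exc,20000,0.21
BLMA_pos,exc,30000,6.75
VP,inh,30000,2.44
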