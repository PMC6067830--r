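region,subpop,time_ms,mfr_hz
AI,exc,10000,1.01
AI,inh,10000,8.01
AI,exc,20000,0.10
AI,inh,20000,1.31
AI,exc,30000,0.32
AI,inh,30000,4.97
PI,exc,10000,1.05
PI,inh,10000,10.09
PI,exc,20000,0.01
PI,inh,20000,2.52
aMCC,exc,10000,1.09
aMCC,inh,10000,5.06
aMCC,exc,20000,1.11
aMCC,inh,20000,6.23
aMCC,exc,30000,1.01
aMCC,inh,30000,4.97
mPFC,exc,10000,0.73
mPFC,inh,10000,4.82
mPFC,exc,20000,1.41
mPFC,inh,20000,10.07
mOFC,exc,30000,1.80
mOFC,inh,30000,12.17
BLMA_neg,exc,10000,0.91
BLMA_neg,exc,20000,0.61
BLMA_neg,exc,30000,0.51
BLMA_pos,exc,20000,7.13
BLMA_pos,exc,30000,9.05
BLMA_i,inh,20000,3.31
BLMA_i,inh,30000,13.62
VP,inh,10000,0.00
VP,inh,20000,2.56
VP,inh,30000,3.56
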