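"source","source_pop","target","target_pop","sign","scope","required"
"AI","exc","AI","inh","excitatory","intra",TRUE
"AI","inh","AI","exc","inhibitory","intra",TRUE
"AI","inh","AI","inh","inhibitory","intra",TRUE
"PI","exc","PI","inh","excitatory","intra",TRUE
"PI","inh","PI","exc","inhibitory","intra",TRUE
"PI","inh","PI","inh","inhibitory","intra",TRUE
"aMCC","exc","aMCC","inh","excitatory","intra",TRUE
"aMCC","inh","aMCC","exc","inhibitory","intra",TRUE
"aMCC","inh","aMCC","inh","inhibitory","intra",TRUE
"mPFC","exc","mPFC","inh","excitatory","intra",TRUE
"mPFC","inh","mPFC","exc","inhibitory","intra",TRUE
"mPFC","inh","mPFC","inh","inhibitory","intra",TRUE
"BLMA_neg","exc","BLMA_neg","inh","excitatory","intra",TRUE
"BLMA_neg","inh","BLMA_neg","exc","inhibitory","intra",TRUE
"BLMA_neg","inh","BLMA_neg","inh","inhibitory","intra",TRUE
"BLMA_pos","exc","BLMA_pos","exc","excitatory","intra",TRUE
"BLMA_pos","exc","BLMA_pos","inh","excitatory","intra",TRUE
"BLMA_pos","inh","BLMA_pos","exc","inhibitory","intra",TRUE
"BLMA_pos","inh","BLMA_pos","inh","inhibitory","intra",TRUE
"mPOA","exc","mPOA","inh","excitatory","intra",TRUE
"mPOA","inh","mPOA","exc","inhibitory","intra",TRUE
"mPOA","inh","mPOA","inh","inhibitory","intra",TRUE
"VP","inh","VP","inh","inhibitory","intra",TRUE
"BLMA_neg","exc","AI","exc","excitatory","inter",TRUE
"AI","exc","aMCC","exc","excitatory","inter",TRUE
"aMCC","exc","AI","exc","excitatory","inter",TRUE
"AI","exc","mPFC","exc","excitatory","inter",TRUE
"mPFC","exc","mPOA","exc","excitatory","inter",TRUE
"mPFC","exc","BLMA_pos","exc","excitatory","inter",TRUE
"mPOA","exc","VTA","da","excitatory","inter",TRUE
"VTA","da","NAc","inh","inhibitory","inter",TRUE
"NAc","inh","VP","inh","inhibitory","inter",TRUE
"BLMA_pos","exc","NAc","inh","excitatory","inter",TRUE
"BLMA_pos","exc","VP","inh","excitatory","inter",TRUE
"BLMA_pos","exc","BLMA_i","inh","excitatory","inter",TRUE
"BLMA_i","inh","BLMA_neg","exc","inhibitory","inter",TRUE
"PI","exc","AI","exc","excitatory","inter",FALSE
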