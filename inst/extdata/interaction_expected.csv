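syn,deg,fwd,rev,init_a0,init_ab,init_b0,exp_a0,exp_ab,exp_b0
FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,0,0,0
TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,1,0,0
FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,0,0,0
TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,1,0,0
FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,0,0,0
TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,1,0,0
FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,0,0,0
TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,1,0,0
FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,0,0,0
TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,1,0,0
FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,0,0,0
TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,1,0,0
FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,0,0,0
TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,1,0,0
FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,0,0,0
TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,1,0,0
FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,1,0,0
TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,1,0,0
FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,0,0,0
TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,1,0,0
FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,1,0,0
TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,1,0,0
FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,0,0,0
TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,1,0,0
FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,1,0,0
TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,1,0,0
FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,0,0,0
TRUE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,1,0,0
FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,1,0,0
TRUE,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,1,0,0
FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,0,0,0
TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,1,0,0
FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,0,1,0
TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,1,1,0
FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,0,0,1
TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,1,0,1
FALSE,FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,0,1,0
TRUE,FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,1,1,0
FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,0,0,1
TRUE,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,1,1,1
FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,1,0,1
TRUE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,1,0,1
FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,0,0,1
TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,1,0,1
FALSE,FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,1,1,1
TRUE,FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,1,1,1
FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,0,0,1
TRUE,TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,1,1,1
FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,1,1,0
TRUE,FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,1,1,0
FALSE,TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,0,0,1
TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,1,0,1
FALSE,FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,1,1,0
TRUE,FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,1,1,0
FALSE,TRUE,TRUE,FALSE,TRUE,TRUE,FALSE,0,0,1
TRUE,TRUE,TRUE,FALSE,TRUE,TRUE,FALSE,1,1,1
FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,1,0,1
TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,1,0,1
FALSE,TRUE,FALSE,TRUE,TRUE,TRUE,FALSE,0,0,1
TRUE,TRUE,FALSE,TRUE,TRUE,TRUE,FALSE,1,0,1
FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,1,1,1
TRUE,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,1,1,1
FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,0,0,1
TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,1,1,1
FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,0,0,1
TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,1,0,1
FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,0,0,1
TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,1,0,1
FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,0,0,1
TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,1,1,0
FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,0,0,1
TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,1,1,1
FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,TRUE,0,0,1
TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,TRUE,1,0,1
FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,TRUE,0,0,1
TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,TRUE,1,0,1
FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,0,0,1
TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,1,1,1
FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE,0,0,1
TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE,1,1,1
FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,1,0,1
TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,1,0,1
FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,TRUE,0,0,1
TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,TRUE,1,0,1
FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,0,1,0
TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,1,1,0
FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,0,0,1
TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,1,1,1
FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,TRUE,1,0,1
TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,TRUE,1,0,1
FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,TRUE,0,0,1
TRUE,TRUE,FALSE,TRUE,TRUE,FALSE,TRUE,1,0,1
FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,1,1,1
TRUE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,1,1,1
FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE,0,0,1
TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE,1,1,1
FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,0,1,1
TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,1,1,1
FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,TRUE,0,0,1
TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,TRUE,1,0,1
FALSE,FALSE,TRUE,FALSE,FALSE,TRUE,TRUE,0,1,1
TRUE,FALSE,TRUE,FALSE,FALSE,TRUE,TRUE,1,1,0
FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,0,0,1
TRUE,TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,1,1,1
FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,TRUE,1,0,1
TRUE,FALSE,FALSE,TRUE,FALSE,TRUE,TRUE,1,0,1
FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,TRUE,0,0,1
TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,TRUE,1,0,1
FALSE,FALSE,TRUE,TRUE,FALSE,TRUE,TRUE,1,1,1
TRUE,FALSE,TRUE,TRUE,FALSE,TRUE,TRUE,1,1,1
FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,TRUE,0,0,1
TRUE,TRUE,TRUE,TRUE,FALSE,TRUE,TRUE,1,1,1
FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,1,1,1
TRUE,FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,1,1,1
FALSE,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,0,0,1
TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,1,0,1
FALSE,FALSE,TRUE,FALSE,TRUE,TRUE,TRUE,0,1,0
TRUE,FALSE,TRUE,FALSE,TRUE,TRUE,TRUE,1,1,0
FALSE,TRUE,TRUE,FALSE,TRUE,TRUE,TRUE,0,0,1
TRUE,TRUE,TRUE,FALSE,TRUE,TRUE,TRUE,1,1,1
FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,1,0,1
TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,1,0,1
FALSE,TRUE,FALSE,TRUE,TRUE,TRUE,TRUE,0,0,1
TRUE,TRUE,FALSE,TRUE,TRUE,TRUE,TRUE,1,0,1
FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,1,1,1
TRUE,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,1,1,1
FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,0,0,1
TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,1,1,1
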