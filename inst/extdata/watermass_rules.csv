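label,t_min,t_max,s_min,s_max,t_min_incl,t_max_incl,s_min_incl,s_max_incl,priority
SW,1,Inf,-Inf,34,FALSE,TRUE,TRUE,FALSE,1
AW,3,Inf,34.9,Inf,FALSE,TRUE,FALSE,TRUE,2
TAW,1,Inf,34.7,34.9,FALSE,TRUE,FALSE,TRUE,3
IW,1,Inf,34,34.7,FALSE,TRUE,TRUE,TRUE,4
ArW,-1.5,1,34.3,34.8,TRUE,TRUE,TRUE,TRUE,5
LW,-0.5,1,34.3,34.85,TRUE,TRUE,TRUE,TRUE,6
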