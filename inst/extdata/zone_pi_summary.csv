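fjord,zone,mean_mgC_m2_day,sd_mgC_m2_day
Hornsund,Glacier,740.4,746.4
Hornsund,Inner,1203.0,604.3
Hornsund,Outer,940.0,807.69
Kongsfjorden,Glacier,111.5,118.0
Kongsfjorden,Inner,486.5,562.2
Kongsfjorden,Outer,769.12,540.53
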