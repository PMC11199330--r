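fjord,zone,variable,min,max,mean,sd
Kongsfjorden,Glacier,pe0_mgC_m3_h,0.12,6.24,2.18,2.75
Kongsfjorden,Glacier,t0_C,0.26,6.7,3.23,2.96
Kongsfjorden,Glacier,sal0_psu,28.16,31.35,29.65,1.36
Kongsfjorden,Glacier,ca0_mgm3,0.56,0.6,0.58,0.03
Kongsfjorden,Inner,pe0_mgC_m3_h,0.01,8.14,2.2,1.88
Kongsfjorden,Inner,t0_C,0.85,6.7,3.76,1.23
Kongsfjorden,Inner,sal0_psu,28.06,31.69,30.4,1.25
Kongsfjorden,Inner,ca0_mgm3,0.2,1.14,0.68,0.37
Kongsfjorden,Outer,pe0_mgC_m3_h,0.19,2.74,1.53,1.28
Kongsfjorden,Outer,t0_C,4.35,6.62,5.69,0.97
Kongsfjorden,Outer,sal0_psu,31.30,34.96,33.48,1.93
Kongsfjorden,Outer,ca0_mgm3,0.23,1.23,0.67,0.51
Hornsund,Glacier,pe0_mgC_m3_h,0.83,12.83,6.0,5.39
Hornsund,Glacier,t0_C,3.51,4.50,3.99,0.54
Hornsund,Glacier,sal0_psu,29.79,30.77,30.28,0.52
Hornsund,Glacier,ca0_mgm3,0.80,1.29,1.05,0.34
Hornsund,Inner,pe0_mgC_m3_h,0.38,13.26,3.49,4.21
Hornsund,Inner,t0_C,1.7,4.9,3.61,1.13
Hornsund,Inner,sal0_psu,29.78,33,31.61,0.87
Hornsund,Inner,ca0_mgm3,0.27,3.47,1.86,1.51
Hornsund,Outer,pe0_mgC_m3_h,1.24,2.40,1.77,0.51
Hornsund,Outer,t0_C,1.75,5.03,4.46,0.64
Hornsund,Outer,sal0_psu,28.5,33.83,33.78,0.06
Hornsund,Outer,ca0_mgm3,0.75,1.46,1.15,0.36
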