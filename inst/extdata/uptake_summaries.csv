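group,time_h,mean_pct_id_g,sd_pct_id_g,n
EBRT+MRT,2,13.50,1.94,3
EBRT+MRT,4,13.43,2.37,3
EBRT+MRT,24,10.47,1.86,3
EBRT+MRT,48,6.73,0.43,3
EBRT+MRT,72,5.43,0.69,2
MRT,2,10.89,4.06,3
MRT,4,10.94,1.80,3
MRT,24,3.57,1.57,3
MRT,48,1.36,0.36,3
MRT,72,0.80,0.15,2
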