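band,n_relocations,chi2_total,df,p_value
JP4645,30,8.58,4,0.072
KGSK2033,23,9.40,4,0.052
LF0216,31,16.21,3,0.001
LF1233,29,6.72,4,0.152
LF1234,30,2.73,2,0.255
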