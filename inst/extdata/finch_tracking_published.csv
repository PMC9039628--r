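band,n_tracking_days,tracking_span_days,n_fixes,n_points,kernel95_ha,kernel50_ha,mcp100_ha,href_m
JP4645,10,13,37,30,7.58,1.17,3.37,46.27
KGSK2033,10,15,41,23,29.09,6.37,17.25,76.54
LF0216,9,14,39,31,14.86,1.90,8.83,55.16
LF1233,7,8,48,29,24.71,4.13,9.50,67.41
LF1234,8,12,54,30,26.47,6.60,11.84,64.57
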