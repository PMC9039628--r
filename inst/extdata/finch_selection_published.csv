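band,habitat,availability,used,expected,chi2_part,usage_prop,ci_low,ci_high,direction,jacobs
JP4645,beach,0.032,1,0.96,0.001,0.033,0,0.118,neutral,0.02
JP4645,inland-water,0.025,0,0.76,0.759,0.000,0,0,negative,-1
JP4645,manzanillo-forest,0.158,1,4.75,2.957,0.033,0,0.118,negative,-0.69
JP4645,dry-forest,0.700,28,21.00,2.333,0.933,0.816,1.051,positive,0.71
JP4645,paved-road,0.084,0,2.53,2.532,0.000,0,0,negative,-1
KGSK2033,beach,0.124,5,2.86,1.596,0.217,0,0.439,neutral,0.32
KGSK2033,inland-water,0.006,0,0.14,0.141,0.000,0,0,negative,-1
KGSK2033,manzanillo-forest,0.430,15,9.90,2.631,0.652,0.396,0.908,neutral,0.43
KGSK2033,dry-forest,0.420,3,9.67,4.599,0.130,0,0.311,negative,-0.66
KGSK2033,paved-road,0.019,0,0.43,0.431,0.000,0,0,negative,-1
LF0216,inland-water,0.018,0,0.57,0.566,0.000,0,0,negative,-1
LF0216,manzanillo-forest,0.428,4,13.28,6.483,0.129,0,0.279,negative,-0.67
LF0216,dry-forest,0.511,27,15.85,7.850,0.871,0.721,1.021,positive,0.73
LF0216,paved-road,0.042,0,1.31,1.309,0.000,0,0,negative,-1
LF1233,beach,0.026,0,0.74,0.743,0.000,0,0,negative,-1
LF1233,inland-water,0.020,0,0.58,0.582,0.000,0,0,negative,-1
LF1233,manzanillo-forest,0.327,5,9.48,2.120,0.172,0,0.353,neutral,-0.40
LF1233,dry-forest,0.600,24,17.41,2.493,0.828,0.647,1.008,positive,0.52
LF1233,paved-road,0.027,0,0.78,0.779,0.000,0,0,negative,-1
LF1234,manzanillo-forest,0.197,5,5.90,0.137,0.167,0.004,0.33,neutral,0
LF1234,dry-forest,0.781,23,23.42,0.008,0.767,0.582,0.952,neutral,-0.04
LF1234,paved-road,0.023,2,0.68,2.589,0.067,0,0.176,neutral,0.51
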