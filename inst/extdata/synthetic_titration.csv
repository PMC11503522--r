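replicate,l_total_uM,f0,f1,f2,f3
1,0,1,0,0,0
1,1,0.5695,0.375,0.0525,0.003
1,2.5,0.264,0.4815,0.2285,0.026
1,5,0.08,0.365,0.4345,0.1205
1,10,0.019,0.2025,0.4685,0.31
1,15,0.008,0.113,0.445,0.434
1,20,0.0035,0.065,0.396,0.5355
1,25,0.003,0.044,0.345,0.608
2,0,1,0,0,0
2,1,0.5735,0.368,0.0555,0.003
2,2.5,0.2755,0.479,0.2195,0.026
2,5,0.097,0.3585,0.424,0.1205
2,10,0.018,0.189,0.4835,0.3095
2,15,0.008,0.1215,0.4195,0.451
2,20,0.0025,0.0715,0.3855,0.5405
2,25,0.0025,0.045,0.3395,0.613
3,0,1,0,0,0
3,1,0.5805,0.363,0.0515,0.005
3,2.5,0.277,0.4775,0.2225,0.023
3,5,0.0885,0.4,0.3955,0.116
3,10,0.0215,0.1935,0.467,0.318
3,15,0.008,0.111,0.431,0.45
3,20,0.0065,0.0665,0.3775,0.5495
3,25,0.0025,0.0495,0.3305,0.6175
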