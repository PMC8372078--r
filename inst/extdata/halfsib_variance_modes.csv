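trait,standardized,va,vday,vmother,vr,h2_mode
killing,FALSE,0.413,0.2434,0.000367,1,0.148
killing,TRUE,1.077,0.3453,0.0009817,1,0.281
attack,FALSE,0.658,0.0179,0.0022149,1,0.223
attack,TRUE,1.886,0.00941,0.001456,1,0.442
lethal_attack,FALSE,2.784,1.0098,0.0010463,1,0.484
lethal_attack,TRUE,4.656,0.6522,0.0015981,1,0.606
successful_parasitism,FALSE,0.01052,0.1963,0.007828,1,0.001757
successful_parasitism,TRUE,0.004270,0.004372,0.00885,1,0.002066
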