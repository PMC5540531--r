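sex,age_low,age_high,year,current,former,never
male,15,25,2002,0.108,0.157,0.735
male,25,35,2002,0.235,0.078,0.687
male,35,45,2002,0.240,0.109,0.651
male,45,55,2002,0.211,0.144,0.644
male,55,65,2002,0.197,0.186,0.616
male,65,75,2002,0.174,0.229,0.597
male,75,Inf,2002,0.224,0.265,0.512
female,15,25,2002,0.069,0.077,0.854
female,25,35,2002,0.008,0.012,0.980
female,35,45,2002,0.010,0.028,0.962
female,45,55,2002,0.028,0.037,0.935
female,55,65,2002,0.053,0.081,0.866
female,65,75,2002,0.042,0.089,0.869
female,75,Inf,2002,0.039,0.072,0.889
male,15,25,2012,0.091,0.134,0.775
male,25,35,2012,0.169,0.317,0.514
male,35,45,2012,0.251,0.387,0.362
male,45,55,2012,0.292,0.490,0.218
male,55,65,2012,0.236,0.476,0.288
male,65,75,2012,0.263,0.457,0.280
male,75,Inf,2012,0.247,0.422,0.331
female,15,25,2012,0.065,0.088,0.847
female,25,35,2012,0.004,0.021,0.976
female,35,45,2012,0.008,0.038,0.955
female,45,55,2012,0.068,0.089,0.843
female,55,65,2012,0.041,0.131,0.828
female,65,75,2012,0.039,0.091,0.870
female,75,Inf,2012,0.039,0.096,0.865
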