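sex,age_low,age_high,mean,sd
male,15,25,-0.0147,0.0076
male,25,35,-0.0144,0.0024
male,35,45,0.0004,0.0079
male,45,55,-0.0177,0.0060
male,55,65,-0.0039,0.0109
male,65,75,-0.0316,0.0108
male,75,Inf,-0.0356,0.0110
female,15,25,-0.1801,0.0089
female,25,35,0.5088,0.0441
female,35,45,0.0199,0.0242
female,45,55,-0.0032,0.0010
female,55,65,0.1200,0.0493
female,65,75,0.0421,0.0441
female,75,Inf,0.0333,0.0474
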