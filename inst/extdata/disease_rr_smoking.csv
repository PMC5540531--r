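disease,sex,age_low,age_high,rr,lci,hci
IHD,male,35,65,2.6,2.4,2.9
IHD,female,35,65,3.2,2.8,3.6
IHD,male,65,Inf,1.5,1.3,1.6
IHD,female,65,Inf,1.7,1.6,1.9
stroke,male,35,65,2.4,1.8,3.0
stroke,female,35,65,3.8,3.1,4.7
stroke,male,65,Inf,1.5,1.2,1.8
stroke,female,65,Inf,1.6,1.4,1.9
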