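intervention,target,measure,value,lci,hci,spread,distribution,sex
advertisement_ban,prevalence,relative_reduction,0.04,NA,NA,0.20,pert,all
advertisement_ban,initiation,relative_risk,0.94,NA,NA,0.20,pert,all
advertisement_ban,cessation,relative_risk,1,NA,NA,NA,point,all
labelling,initiation,relative_risk,0.67,0.49,0.87,NA,lognormal,all
labelling,cessation,relative_risk,1.99,1.29,3.05,NA,lognormal,all
smoke_free_public,initiation,relative_risk,0.83,0.57,1.22,NA,lognormal,male
smoke_free_public,initiation,relative_risk,0.86,0.59,1.26,NA,lognormal,female
smoke_free_public,cessation,relative_risk,1.09,0.91,1.30,NA,lognormal,all
smoke_free_workplace,initiation,relative_risk,1,NA,NA,NA,point,all
smoke_free_workplace,cessation,relative_risk,2.29,1.56,3.37,NA,lognormal,all
mass_media,initiation,relative_risk,0.8,0.71,0.91,NA,lognormal,all
mass_media,cessation,relative_risk,1.1,0.98,1.24,NA,lognormal,all
tobacco_tax,prevalence,price_elasticity,-0.88,-0.78,-0.37,NA,lognormal,all
tobacco_tax,initiation,price_elasticity,-1.175,NA,NA,0.20,pert,all
tobacco_tax,cessation,price_elasticity,0,NA,NA,NA,point,all
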