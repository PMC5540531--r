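intervention,cost,dalys_male,dalys_female,dalys_total,acer,icer
no_intervention,0,0,0,0,0,NA
tobacco_tax,1547355,249126,38706,287832,5,5
mass_media,1996026,33018,19664,52682,38,Dominated
labelling,2248370,44903,11269,56174,40,Dominated
advertisement_ban,2164048,19894,2438,22332,97,Dominated
smoke_free_public,3646117,31021,4294,35315,103,Dominated
smoke_free_workplace,3381652,5681,6985,12666,267,Dominated
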