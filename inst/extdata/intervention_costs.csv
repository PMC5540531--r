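cost_center,advertisement_ban,labelling,smoke_free,mass_media,tobacco_tax
program_development,52710,52710,52710,0,145535
human_resources,1545666,1513731,2345066,330694,1464615
promotion_media_advocacy,107267,107267,107267,739172,7765
program_supplies,0,0,0,89115,0
rent_equipment_office,30131,28783,30131,71133,21860
operations,885042,885042,885042,885042,27170
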