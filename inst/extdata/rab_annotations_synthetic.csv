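rab_id,pd_linked,thr_active_site,in_vitro_phospho,secretory_organelle
Rab1,TRUE,TRUE,FALSE,TRUE
Rab2,FALSE,TRUE,FALSE,TRUE
Rab3,TRUE,TRUE,TRUE,TRUE
Rab4,FALSE,FALSE,FALSE,FALSE
Rab5,FALSE,TRUE,TRUE,FALSE
Rab6,FALSE,TRUE,FALSE,TRUE
Rab7,TRUE,FALSE,FALSE,FALSE
Rab8,TRUE,TRUE,TRUE,TRUE
Rab9,FALSE,FALSE,FALSE,FALSE
Rab10,TRUE,TRUE,TRUE,TRUE
Rab11,FALSE,FALSE,TRUE,TRUE
Rab14,TRUE,TRUE,FALSE,FALSE
Rab18,FALSE,FALSE,FALSE,FALSE
Rab19,FALSE,TRUE,FALSE,FALSE
Rab21,FALSE,FALSE,FALSE,FALSE
Rab23,FALSE,FALSE,FALSE,FALSE
Rab26,TRUE,TRUE,FALSE,TRUE
Rab27,TRUE,TRUE,FALSE,TRUE
Rab30,FALSE,TRUE,FALSE,TRUE
Rab32,TRUE,FALSE,TRUE,FALSE
Rab35,TRUE,TRUE,TRUE,FALSE
Rab39,FALSE,TRUE,FALSE,FALSE
Rab40,FALSE,FALSE,FALSE,FALSE
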