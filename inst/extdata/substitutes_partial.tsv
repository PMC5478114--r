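gene	substitute	substitute_pathway	same_pathway
Npy	Spink5	Cell Migration	TRUE
Ccr2	Ctss	Immune Response	TRUE
CD180	Aim2	Immune Response	TRUE
CD72	CD48	Immune Response	TRUE
Chaf1b	Kif11	Cell Cycle	TRUE
Nrp1	Klrd1	Cell Migration	TRUE
Cldn8	Clu	Cell Death	FALSE
St8sia4	Ncf4	Immune Response	FALSE
Scrn1	Mphosph6	NA	FALSE
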