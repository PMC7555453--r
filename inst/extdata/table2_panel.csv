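species_scope,assay,target_gene,primer_name,amplicon_bp,fluorophore
universal,mpcr,cytochrome_b_mtDNA,SIM,NA,NA
beef,mpcr,cytochrome_b_mtDNA,B,274,NA
pork,mpcr,cytochrome_b_mtDNA,P,398,NA
chicken_turkey,mpcr,cytochrome_b_mtDNA,C,169,NA
horse,mpcr,cytochrome_b_mtDNA,H,439,NA
beef,mqpcr,cyclic_GMP_phosphodiesterase_gDNA,Bos-PDE,104,TexasRed
pork,mqpcr,beta_actin_gDNA,Sus1,107,HEX
mammals_poultry,mqpcr,myostatin_gDNA,MY,97,FAM
chicken,mqpcr,interleukin_2_gDNA,ChIn,135,TAMRA
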