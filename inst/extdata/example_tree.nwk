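((((Homo_sapiens_syn:0.02,Pan_troglodytes_syn:0.03)0.99:0.05,(Mus_musculus_syn:0.10,Rattus_norvegicus_syn:0.09)0.97:0.08)0.95:0.04,(Gallus_gallus_syn:0.12,Danio_rerio_syn:0.20)0.90:0.03)0.98:0.15,((Saccharomyces_cerevisiae_syn:0.45,Dictyostelium_discoideum_syn:0.40)0.55:0.05,(((Arabidopsis_thaliana_syn:0.08,(Oryza_sativa_syn:0.03,Zea_mays_syn:0.04)0.99:0.06)0.96:0.10,Physcomitrella_patens_syn:0.20)0.92:0.12,(Plasmodium_falciparum_syn:0.50,Cyanidioschyzon_merolae_syn:0.35)0.65:0.07)0.75:0.04)0.60:0.02);
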