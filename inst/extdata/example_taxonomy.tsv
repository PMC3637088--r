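# Synthetic example data: OTU names and lineages are constructed for the
# package documentation and do not correspond to real sequence accessions.
# Format: <otu_name><TAB><rank1>;<rank2>;...   (rank 1 = most inclusive)
Homo_sapiens_syn	Eukaryota;Metazoa;Chordata;Homo
Pan_troglodytes_syn	Eukaryota;Metazoa;Chordata;Pan
Mus_musculus_syn	Eukaryota;Metazoa;Chordata;Mus
Rattus_norvegicus_syn	Eukaryota;Metazoa;Chordata;Rattus
Gallus_gallus_syn	Eukaryota;Metazoa;Chordata;Gallus
Danio_rerio_syn	Eukaryota;Metazoa;Chordata;Danio
Saccharomyces_cerevisiae_syn	Eukaryota;Fungi;Ascomycota;Saccharomyces
Dictyostelium_discoideum_syn	Eukaryota;Amoebozoa;Mycetozoa;Dictyostelium
Arabidopsis_thaliana_syn	Eukaryota;Viridiplantae;Tracheophyta;Arabidopsis
Oryza_sativa_syn	Eukaryota;Viridiplantae;Tracheophyta;Oryza
Zea_mays_syn	Eukaryota;Viridiplantae;Tracheophyta;Zea
Physcomitrella_patens_syn	Eukaryota;Viridiplantae;Bryophyta;Physcomitrella
Plasmodium_falciparum_syn	Eukaryota;Alveolata;Apicomplexa;Plasmodium
Cyanidioschyzon_merolae_syn	Eukaryota;Rhodophyta;Bangiophyceae;Cyanidioschyzon
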