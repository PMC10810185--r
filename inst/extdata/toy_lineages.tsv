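Homo_sapiens	Eukaryota;Opisthokonta;Metazoa;Chordata;Mammalia;Homo sapiens
Mus_musculus	Eukaryota;Opisthokonta;Metazoa;Chordata;Mammalia;Mus musculus
Drosophila_melanogaster	Eukaryota;Opisthokonta;Metazoa;Arthropoda;Insecta;Drosophila melanogaster
Caenorhabditis_elegans	Eukaryota;Opisthokonta;Metazoa;Nematoda;Chromadorea;Caenorhabditis elegans
Saccharomyces_cerevisiae	Eukaryota;Opisthokonta;Fungi;Ascomycota;Saccharomycetes;Saccharomyces cerevisiae
Arabidopsis_thaliana	Eukaryota;Viridiplantae;Streptophyta;Magnoliopsida;Brassicales;Arabidopsis thaliana
Chlamydomonas_reinhardtii	Eukaryota;Viridiplantae;Chlorophyta;Chlorophyceae;Chlamydomonadales;Chlamydomonas reinhardtii
Trypanosoma_brucei	Eukaryota;Discoba;Euglenozoa;Kinetoplastea;Trypanosomatida;Trypanosoma brucei
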