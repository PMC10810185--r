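(((XPA_Homo_sapiens,XPA_Mus_musculus),(XPA_Drosophila_melanogaster,XPA_Caenorhabditis_elegans)),((XPA2_Homo_sapiens,XPA2_Mus_musculus),XPA_Saccharomyces_cerevisiae));
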