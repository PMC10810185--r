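>XPA_Homo_sapiens synthetic toy alignment, not the real XPA
MEKCC-RPLCAETKCCV
>XPA_Mus_musculus synthetic
MEKCCARPLCAETKCCV
>XPA_Drosophila_melanogaster synthetic
MDKCC-RPICAESKCCI
>XPA_Caenorhabditis_elegans synthetic
MEKCC-KPLCADTKCCV
>XPA_Saccharomyces_cerevisiae synthetic
MSKCC-RPLCSETKCCL
>ZNT9_like_outgroup synthetic remote homolog lacking the signature
MSKAA-RPLASETKAAV
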