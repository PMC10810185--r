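Package: xrquant
Title: Quantitative Excision Repair Sequencing (qXR-Seq) Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of quantitative excision repair sequencing
    (qXR-Seq) libraries: adaptor trimming, duplicate removal and exact-match
    alignment of excised-oligonucleotide reads; selection of reads carrying the
    nucleotide-excision-repair damage signature (a dipyrimidine 4-10 nt from the
    3' end); per-position nucleotide and dinucleotide composition profiles with
    a mitochondrial internal control; strand-resolved unit-gene metagene
    profiles of transcription-coupled repair; and cross-species spike-in
    quantification of relative repair activity via a wild-type dilution-series
    calibration. Includes a ground-truth synthetic data generator so the whole
    pipeline runs and is testable without external sequencing data, and
    phylogenetic tree annotation utilities (lineage labelling, species-overlap
    duplication nodes, presence/absence matrices, signature-residue
    conservation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
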