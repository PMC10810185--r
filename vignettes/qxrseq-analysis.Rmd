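---
title: "Quantitative excision-repair sequencing analysis with xrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative excision-repair sequencing analysis with xrquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrquant)
```

## The assay and the analysis model

Nucleotide excision repair removes helix-distorting DNA lesions -- chiefly the
UV photoproducts CPD and (6-4)PP, both of which form at adjacent pyrimidines
-- by dual incision, releasing a ~20-30 nt single-stranded oligomer that
contains the lesion. Excision-repair sequencing captures and sequences these
excised oligomers directly, so each read is one repair event with two
diagnostic properties:

1. **A positional damage signature.** The 3' incision falls a fixed distance
   from the lesion, so the dipyrimidine sits near the read's 3' end -- in
   practice with both bases 4-10 nt from the 3' terminus (offset 1 = the
   3'-terminal base), peaking with the pair's bases at offsets 5-6. Mapped
   mitochondrial reads, which are not products of nuclear excision repair,
   lack this signature and serve as the internal specificity control.
2. **A strand asymmetry in genes.** Transcription-coupled repair (TCR)
   preferentially repairs the transcribed strand (TS) of active genes. An
   excised oligo from the TS maps *antisense* to the gene annotation -- the
   read strand opposite the gene strand is the TS signal (the bedtools
   `-S` convention). This is the reverse of naive intuition and is stated
   wherever strand classes appear in this package.

The quantitative variant of the assay adds a fixed amount of excised-oligo
material from a second species ("spike-in") to every sample before library
construction. Because the spike-in is constant, the ratio

$$R = \frac{n_\text{sample}}{n_\text{spike}}$$

of filtered read counts is proportional to the amount of excised oligos in the
sample, independent of sequencing depth. A serial dilution of the wild-type
sample (e.g. 1, 1/10, ..., 1/10,000 with the same spike-in) calibrates the
scale: the ratio must vanish at dilution zero, so the calibration is a least
squares line through the origin,

$$\hat{\beta} = \frac{\sum_i d_i R_i}{\sum_i d_i^2},$$

and any library's repair relative to wild type is
$100 \cdot (R / \hat\beta) / s$ percent, where the input scale $s$ corrects
deliberate loading differences (repair-deficient lines are typically loaded
with ~2000x more starting material so that their few excised oligos are
detectable; their measured ratio is inflated by the same factor). Fold over
background divides the percent of a +UV condition by the matched no-UV
condition. An intercept fit and a log-log (geometric-mean) fit are available
behind `method =` in `fit_dilution_curve()` for series spanning a very wide
dynamic range; the through-origin linear fit is the default because the
physical model forces the line through zero.

## Pipeline stages and their parameters

**Read processing** (`process_reads()`): adaptor trimming (longest exact
suffix/prefix match, `min_overlap = 3`), duplicate removal on sequence
identity (PCR collapse; performed after trimming so adaptor-bearing copies of
one molecule collapse), exact-match alignment, length filtering, and trimming
to a common 20 nt. The bundled aligner reports a read only when its sequence
(or reverse complement) occurs exactly once across both strands of the genome;
it is intended for the synthetic genomes used here, and real data should
arrive pre-aligned as BED6 via `read_bed6_reads()`. All coordinates are
0-based half-open (BED convention) throughout, and read sequences are always
stored read-oriented (5'->3' of the excised oligo), i.e. reverse-complemented
relative to the reference on the minus strand -- all positional damage logic
is defined on the oligo, not the reference.

**3'-anchored trimming.** `trim_5prime_to(reads, k = 20)` removes bases from
the 5' end, keeping the 3'-terminal 20 nt. Because the 3' incision is anchored
to the lesion, this preserves the 3'-offset of every remaining base, which is
what makes composition profiles comparable across read lengths of different
species (24-30 nt in human, 20-28 nt in worm, 25-30 nt in fly). Trimming the
other way (keeping the first 20 bases) would smear the damage peak across
positions for mixed-length input.

**Length windows.** Species presets (`species_length_range()`) encode the
ranges above; `auto_select_range()` rediscovers a window from the data by
scoring, per length, the fraction of reads whose bases at 3'-offsets 5-6 form
a pyrimidine pair, then taking the contiguous run around the best length whose
members all score at least half the maximum. Two guard rails: lengths with
fewer than 100 reads are not scored, and if no length scores above 0.5 the
configured species default is used instead -- at a fixed position pair, random
sequence scores ~0.25, so a signature-free library can never clear the 0.5
bar and always falls back rather than returning a meaningless window.

**Damage filtering** (`filter_damage()`): keeps reads with two adjacent
pyrimidines whose bases both lie at 3'-offsets 4-10. The window is a
parameter; the alternative reading in which only the pair's *start* position
must lie in the window is one flag away (widen the window by one). Note the
filter enriches rather than purifies: a random 20-mer has ~75% chance of a
pyrimidine pair somewhere in the seven-pair window, so background libraries
retain substantial fractions -- the specificity evidence is positional
(composition profiles), not the pass rate.

**Composition profiles** (`nucleotide_matrix()`, `dinucleotide_profile()`):
per-position base counts for each read length, and 16-dinucleotide frequencies
per position of the 20-trimmed reads, split nuclear vs mitochondrial, plus the
aggregate pyrimidine-pair frequency (TT+TC+CT+CC). Pair positions are reported
both 5'-anchored and as the 3'-offset of the pair's 3'-most base; both full
tables are written because whether to display all 16 dinucleotides or only
the 4 pyrimidine pairs is a presentation choice.

**Metagene profiles** (`metagene_profile()`): genes are selected by length and
isolation (human 5 kb / 5 kb; worm 1 kb / 500 bp; fly 1 kb / 100 bp; distances
are edge-to-edge and strand-ignorant, so any positive distance threshold also
removes overlapping genes), then divided into 150 bins: 25 x 80 bp upstream,
100 near-equal body bins, 25 x 80 bp downstream, ordered 5'->3' of the gene so
bin 1 is always 2 kb upstream of the TSS. The body remainder `r = L mod 100`
goes to the last `r` body bins, making binning deterministic. Reads count in a
bin when the overlap covers at least half the read (`>=`, the bedtools
`-F 0.5` semantics), so a read lands in at most 2 bins. Genes are ranked by
the wild-type per-gene `(TS+1)/(NTS+1)` ratio (the pseudocount handles empty
genes; ties break by total reads then gene id) and the top 5000 kept; each
bin's value is the mean over those genes of reads per kilobase of bin per
million total filtered reads.

Two numerical caveats are worth knowing. First, flank bins running past a
contig edge are clipped (the gene is kept and flagged); zero-width bins are
excluded from the per-bin mean. Second, because the remainder rule is
gene-oriented, flipping a gene's annotated strand shifts body-bin boundaries
by up to 1 bp unless the length is a multiple of 100; the strand-swap symmetry
(flipping all strands exchanges TS and NTS and reverses bin order) is
therefore exact on genes with lengths divisible by 100, which is how the test
suite asserts it.

## The synthetic data generator

`simulation_params()` + `make_genome()`/`make_genes()`/`simulate_library()`
emulate the statistical structure the analysis assumes, with a ground-truth
manifest recording every molecule's origin, strand class, signal flag and
damage offset:

- reads of 19-30 nt (uniform length weights by default -- the real, species
  specific length distribution is not published, so the least-informative
  choice is used and is overridable);
- a fraction `signal_fraction` (default 0.9) of nuclear reads carry the
  signature: they are placed *inside genes* at positions where the reference
  itself contains a pyrimidine pair at the drawn 3'-offset (rejection
  sampling, ~4 draws per read on random sequence; the genome is never mutated
  so exact alignment recovers every read), with offset weights 0.5/0.5 over
  3'-offsets 5 and 6 of the pair's 3' base;
- signal reads fall on the transcribed strand with odds `tcr_ratio` (default
  4:1, a clearly detectable but not extreme TCR bias);
- `mito_fraction` (default 5%) of reads come from chrM and are always
  signature-free background, reproducing the mitochondrial specificity
  control;
- raw reads carry a full 3' adaptor and are duplicated with probability
  `duplicate_rate` (default 0.2);
- `make_spikein_series()` thins the base library binomially per dilution
  (the statistical analogue of serial dilution) and adds exactly
  `spike_reads` molecules from a second-genome library.

What the generator does *not* emulate: sequencing errors and quality scores,
species-realistic base composition and repeats (the uniform random genome
makes exact alignment nearly lossless, which real genomes are not),
photoproduct-specific chemistry, and transcription-level heterogeneity across
genes (all genes share one TCR odds ratio). Tests passing on synthetic data
therefore validate the *computations* -- filters, binning, strand logic,
calibration algebra -- not the biology of any particular genome.

The defaults above, together with the counts-level calibration experiment
(`simulate_count_series()`: 5-point series 1...1/10,000, ~5000 expected
spike reads, true slope 500, a mutant at 1% of wild type, Poisson counts),
are the study conditions used by the test suite and by
`scripts/acceptance.R`; problem sizes there (8000-read libraries, 150-200 kb
genomes, 10-20 replicate seeds) were chosen as the smallest sizes at which
the binomial/Poisson error bands in the checks are comfortably narrower than
the effects being recovered.

## Phylogenetic annotation

The tree utilities implement the custom curation steps used to map gene
presence across a large species phylogeny, downstream of standard external
tools (homology search, alignment, tree inference are out of scope):

- `add_lineage()` labels each internal node with the deepest taxonomic level
  shared by all species below it, computed positionally on root-first lineage
  vectors. The phrase "most common lowest taxonomic level" also admits a
  frequency reading (the most frequent lowest taxon); the LCA reading is
  implemented because it is the one that makes labels monotone from root to
  tips, and the brute-force set-intersection oracle in the tests pins the
  behaviour down.
- `label_duplication_nodes()` flags a node as a gene duplication when its
  child clades share more than one species (`min_shared = 2`). This is
  deliberately stricter than the classical species-overlap rule (any shared
  species) to resist single-species artifacts such as contaminated or
  misassigned sequences; the classical rule is `min_shared = 1`.
  Multifurcations are evaluated over all child pairs. Rooting, outgroup
  choice and clade pruning remain manual inputs: the module annotates a tree,
  it does not root one.
- `signature_conservation()` maps reference positions through the reference
  row's gaps to alignment columns and scores each sequence by the fraction of
  signature columns carrying the required residue. The default signature is
  the conserved XPA-family cysteines at human XPA positions 105-108, 126-128
  and 261-264, with a 0.7 pass fraction -- strict enough to reject remote
  homologs lacking the zinc-binding cysteines, tolerant of a few alignment
  wobbles.
- `presence_absence()` and `clade_presence_summary()` tabulate accepted
  homologs per species and clade.

## Worked example

```{r demo, eval = FALSE}
library(xrquant)
report <- run_all(default_config(seed = 1))
report$quant          # percent-of-WT per library
report$fit$slope      # calibration slope (undiluted WT ratio)
head(report$profile)  # 150-bin TS/NTS metagene
```

The demo configuration simulates a worm-like sample with a fly-like spike-in
(3-point dilution series plus a mutant at 1% of wild type), processes every
library through trimming, deduplication, cross-species partitioning and both
filters, and writes profiles, quantification tables and a stage report, all
byte-reproducibly for a fixed seed.

## Known limitations

- The exact aligner is for synthetic genomes; align real reads externally and
  ingest BED6.
- Adaptor matching is exact; error-containing adaptors should be trimmed
  upstream.
- How multi-mapping reads were treated upstream of BED ingestion is the
  caller's responsibility; the bundled aligner drops them.
- The dipyrimidine window interpretation ("both bases inside 4-10") and the
  overlap-threshold semantics (`>=` 50% of the read) are parameters/documented
  choices, not discoveries; alternatives are one argument away.
- Percentages from real experiments depend on genome annotations and
  sequencing depth; this package validates its computations on synthetic
  ground truth only.
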