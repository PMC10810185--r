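# shared fixtures built in code

# deterministic random DNA of length n
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_dna_vec <- function(n_seq, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_seq), function(i) rand_dna(len), character(1))
}

write_tmp <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}

# small lineage map used by the phylo tests
toy_lineages <- function() {
  list(
    Human = c("Eukaryota", "Metazoa", "Chordata", "Mammalia", "Homo"),
    Mouse = c("Eukaryota", "Metazoa", "Chordata", "Mammalia", "Mus"),
    Fly   = c("Eukaryota", "Metazoa", "Arthropoda", "Drosophila"),
    Worm  = c("Eukaryota", "Metazoa", "Nematoda", "Caenorhabditis"),
    Yeast = c("Eukaryota", "Fungi", "Ascomycota", "Saccharomyces"),
    Plant = c("Eukaryota", "Viridiplantae", "Streptophyta", "Arabidopsis"))
}

# random taxonomy + lineages for the brute-force tree oracles
random_taxonomy <- function(n_species, seed) {
  set.seed(seed)
  lapply(setNames(seq_len(n_species), paste0("sp", seq_len(n_species))),
         function(i) {
           l1 <- sample(c("CladeA", "CladeB"), 1)
           l2 <- paste0(l1, "_", sample(1:3, 1))
           l3 <- paste0(l2, "_", sample(1:2, 1))
           c("Root", l1, l2, l3, paste0("sp", i))
         })
}

# brute-force lineage LCA: deepest taxon present in every species' lineage set
oracle_lineage_lca <- function(lineages) {
  shared <- Reduce(intersect, lineages)
  first <- lineages[[1]]
  first[max(match(shared, first))]
}

# brute-force O(n^2) nearest-gene distance filter
oracle_select_genes <- function(genes, min_length, min_distance) {
  keep <- vapply(seq_len(nrow(genes)), function(i) {
    if (genes$end[i] - genes$start[i] < min_length) return(FALSE)
    others <- genes[-i, ]
    others <- others[others$contig == genes$contig[i], ]
    if (nrow(others) == 0) return(TRUE)
    d <- pmax(pmax(others$start - genes$end[i],
                   genes$start[i] - others$end), 0)
    min(d) >= min_distance
  }, logical(1))
  genes$gene_id[keep]
}

# brute-force dipyrimidine scan over all adjacent pairs and offset windows
oracle_dipyrimidine <- function(seq, lo = 4, hi = 10) {
  if (grepl("N", seq, fixed = TRUE)) return(FALSE)
  L <- nchar(seq)
  for (i in seq_len(L - 1)) {
    off1 <- L - i + 1  # 3'-offset of base i
    off2 <- L - i      # 3'-offset of base i + 1
    both_in <- off1 >= lo && off1 <= hi && off2 >= lo && off2 <= hi
    pair <- substring(seq, i, i + 1)
    if (both_in && pair %in% c("CC", "CT", "TC", "TT")) return(TRUE)
  }
  FALSE
}
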