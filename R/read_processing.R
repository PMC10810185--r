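#' Species length-range presets
#'
#' Excised-oligo length windows with the best dipyrimidine enrichment, per
#' species: human 24-30 nt, worm (C. elegans) 20-28 nt, fly (D. melanogaster)
#' 25-30 nt. The generic window is 19-30 nt.
#'
#' @param species `"human"`, `"worm"`, `"fly"` or `"generic"`.
#' @return integer vector `c(lo, hi)`.
#' @export
species_length_range <- function(species = c("human", "worm", "fly",
                                             "generic")) {
  species <- match.arg(species)
  switch(species,
         human = c(24L, 30L),
         worm = c(20L, 28L),
         fly = c(25L, 30L),
         generic = c(19L, 30L))
}

.check_length_range <- function(range) {
  stopifnot(length(range) == 2, range[1] <= range[2],
            range[1] >= 19, range[2] <= 30)
  as.integer(range)
}

#' Trim the 3' sequencing adaptor from raw reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adaptor, requiring at least `min_overlap` matching bases. Reads with no
#' adaptor evidence pass unchanged; reads that are all adaptor (empty after
#' trimming) are discarded. Matching is exact: synthetic libraries are
#' error-free, and real data should be adaptor-trimmed upstream.
#'
#' @param reads raw-read data.frame (`read_id`, `sequence`).
#' @param adaptor adaptor sequence.
#' @param min_overlap minimum suffix/prefix match length.
#' @return trimmed raw-read data.frame; `attr(, "stats")` holds
#'   `c(input, trimmed, discarded)`.
#' @export
trim_adaptor <- function(reads, adaptor, min_overlap = 3L) {
  if (nchar(adaptor) == 0) stop("adaptor must be non-empty")
  seqs <- reads$sequence
  n <- nchar(seqs)
  matched <- integer(length(seqs))
  for (k in seq(min_overlap, nchar(adaptor))) {
    pref <- substr(adaptor, 1, k)
    hit <- n >= k & substring(seqs, n - k + 1, n) == pref
    matched[hit] <- k
  }
  trimmed <- substr(seqs, 1, n - matched)
  keep <- nchar(trimmed) > 0
  out <- data.frame(read_id = reads$read_id[keep], sequence = trimmed[keep])
  attr(out, "stats") <- c(input = length(seqs), trimmed = sum(matched > 0),
                          discarded = sum(!keep))
  out
}

#' Remove exact duplicate reads
#'
#' Keeps the first occurrence of every distinct sequence (sequence-only
#' collapsing, as done before alignment). Idempotent.
#'
#' @param reads raw-read data.frame.
#' @return deduplicated raw-read data.frame; `attr(, "stats")` holds
#'   `c(input, unique)`.
#' @export
dedup <- function(reads) {
  keep <- !duplicated(reads$sequence)
  out <- reads[keep, ]
  rownames(out) <- NULL
  attr(out, "stats") <- c(input = nrow(reads), unique = sum(keep))
  out
}

# Exact-match hit counting over both strands of a genome, grouped by read
# length so Biostrings::PDict can be used. Returns per-sequence total hit
# count and, for reads seen at least once, the first hit's location.
.exact_hits <- function(seqs, genome) {
  n <- length(seqs)
  hits <- integer(n)
  contig <- character(n); start <- integer(n); strand <- character(n)
  if (n == 0) {
    return(data.frame(hits = hits, contig = contig, start = start,
                      strand = strand))
  }
  subjects <- lapply(genome, Biostrings::DNAString)
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    ii <- which(lens == L)
    ss <- Biostrings::DNAStringSet(seqs[ii])
    pd_f <- Biostrings::PDict(ss)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(ss))
    for (ctg in names(genome)) {
      for (sd in c("+", "-")) {
        m <- Biostrings::matchPDict(if (sd == "+") pd_f else pd_r,
                                    subjects[[ctg]])
        cnt <- S4Vectors::elementNROWS(m)
        st <- Biostrings::startIndex(m)
        got <- which(cnt > 0)
        for (j in got) {
          idx <- ii[j]
          if (hits[idx] == 0) {
            contig[idx] <- ctg
            start[idx] <- st[[j]][1] - 1L  # 0-based
            strand[idx] <- sd
          }
          hits[idx] <- hits[idx] + cnt[j]
        }
      }
    }
  }
  data.frame(hits = hits, contig = contig, start = start, strand = strand)
}

#' Exact-match alignment of reads to a genome
#'
#' A deliberately simple aligner for synthetic genomes: a read is reported if
#' and only if its sequence (or reverse complement) occurs exactly once across
#' both strands of the genome. Multi-hit and unmapped reads are dropped and
#' counted, as are reads containing N. Real data should arrive pre-aligned via
#' [read_bed6_reads()].
#'
#' @param reads raw-read data.frame.
#' @param genome named character vector of contig sequences.
#' @param sample_id sample label for the output.
#' @return aligned-read data.frame; `attr(, "stats")` holds
#'   `c(input, aligned, multi, unmapped, with_n)`.
#' @export
align_exact <- function(reads, genome, sample_id = "sample") {
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  clean <- reads[!has_n, ]
  h <- .exact_hits(clean$sequence, genome)
  uniq <- h$hits == 1
  L <- nchar(clean$sequence)
  out <- aligned_reads(clean$read_id[uniq], h$contig[uniq], h$start[uniq],
                       h$start[uniq] + L[uniq], h$strand[uniq],
                       clean$sequence[uniq], sample_id)
  attr(out, "stats") <- c(input = nrow(reads), aligned = sum(uniq),
                          multi = sum(h$hits > 1), unmapped = sum(h$hits == 0),
                          with_n = sum(has_n))
  out
}

#' Filter reads by length
#'
#' @param reads aligned-read (or raw-read) data.frame.
#' @param range integer `c(lo, hi)` with `19 <= lo <= hi <= 30`, or a species
#'   name accepted by [species_length_range()].
#' @return filtered data.frame; `attr(, "stats")` holds `c(input, kept)`.
#' @export
filter_length <- function(reads, range = c(19L, 30L)) {
  if (is.character(range)) range <- species_length_range(range)
  range <- .check_length_range(range)
  L <- nchar(reads$sequence)
  keep <- L >= range[1] & L <= range[2]
  out <- reads[keep, ]
  rownames(out) <- NULL
  attr(out, "stats") <- c(input = nrow(reads), kept = sum(keep))
  out
}

#' Trim reads to a common length, anchored at the 3' end
#'
#' Removes bases from the 5' end so that every read is exactly `k` nt. The 3'
#' terminus is the biologically anchored end of an excised oligo (the 3'
#' incision sits a fixed distance from the lesion), so trimming from the 5'
#' side preserves the 3'-offset of every remaining base -- the property all
#' downstream damage-position logic relies on. Coordinates shrink on the
#' genomic side corresponding to the read's 5' end: plus-strand reads keep
#' `[end - k, end)`, minus-strand reads keep `[start, start + k)`.
#'
#' @param reads aligned-read data.frame; every read must be at least `k` nt.
#' @param k target length (default 20, the cross-species comparison length).
#' @return trimmed aligned-read data.frame.
#' @export
trim_5prime_to <- function(reads, k = 20L) {
  L <- nchar(reads$sequence)
  if (any(L < k)) {
    stop(sum(L < k), " read(s) shorter than k = ", k,
         "; filter by length first")
  }
  reads$sequence <- substring(reads$sequence, L - k + 1, L)
  plus <- reads$strand == "+"
  reads$start[plus] <- reads$end[plus] - as.integer(k)
  reads$end[!plus] <- reads$start[!plus] + as.integer(k)
  reads
}

#' Choose a read-length range from dipyrimidine enrichment
#'
#' For each length 19..30 with at least `min_reads` reads, scores the fraction
#' of reads whose bases at 3'-offsets 5 and 6 form a pyrimidine dinucleotide
#' (the expected damage position). Returns the contiguous run of lengths
#' around the best-scoring length whose members all score at least half the
#' maximum. Falls back to `default` when no length has enough reads or when no
#' length shows enrichment above `flat_threshold` (random sequence scores
#' ~0.25 at a fixed position pair, so a flat, signature-free library never
#' clears 0.5).
#'
#' @param reads aligned-read or raw-read data.frame.
#' @param default fallback range (species preset).
#' @param min_reads minimum reads per length for that length to be scored.
#' @param flat_threshold minimum best score for the data-driven range to be
#'   trusted.
#' @return integer `c(lo, hi)`.
#' @export
auto_select_range <- function(reads, default = c(19L, 30L), min_reads = 100L,
                              flat_threshold = 0.5) {
  if (is.character(default)) default <- species_length_range(default)
  lens <- 19:30
  L <- nchar(reads$sequence)
  score <- rep(NA_real_, length(lens))
  for (i in seq_along(lens)) {
    ii <- which(L == lens[i])
    if (length(ii) < min_reads) next
    pair <- substring(reads$sequence[ii], lens[i] - 5, lens[i] - 4)
    score[i] <- mean(pair %in% PYRIMIDINE_PAIRS)
  }
  if (all(is.na(score))) return(.check_length_range(default))
  mx <- max(score, na.rm = TRUE)
  if (mx < flat_threshold) return(.check_length_range(default))
  qual <- !is.na(score) & score >= 0.5 * mx
  best <- which.max(score)
  lo <- best
  while (lo > 1 && qual[lo - 1]) lo <- lo - 1
  hi <- best
  while (hi < length(lens) && qual[hi + 1]) hi <- hi + 1
  c(lens[lo], lens[hi])
}

#' Run the stage-1 read-processing pipeline
#'
#' Adaptor trimming -> duplicate removal -> exact unique alignment -> length
#' filtering -> 5'-side trimming to a common 20 nt. Trimming precedes
#' deduplication so that adaptor-bearing copies of the same molecule collapse.
#'
#' @param raw raw-read data.frame (e.g. from [read_fastq()] or a simulated
#'   library's `$raw`).
#' @param genome named character vector of contig sequences.
#' @param adaptor 3' adaptor sequence.
#' @param range length range `c(lo, hi)`, a species name, or `"auto"` to use
#'   [auto_select_range()] with `auto_default` as fallback.
#' @param k common trimmed length; `NA` skips trimming.
#' @param min_overlap adaptor match minimum.
#' @param auto_default fallback range for `range = "auto"`.
#' @param sample_id sample label.
#' @return list with `reads` (processed aligned reads), `range` (the length
#'   range used) and `report` (per-stage read counts).
#' @export
process_reads <- function(raw, genome, adaptor, range = "auto", k = 20L,
                          min_overlap = 3L, auto_default = c(19L, 30L),
                          sample_id = "sample") {
  trimmed <- trim_adaptor(raw, adaptor, min_overlap)
  uniq <- dedup(trimmed)
  aligned <- align_exact(uniq, genome, sample_id)
  if (identical(range, "auto")) {
    range <- auto_select_range(aligned, default = auto_default)
  } else if (is.character(range)) {
    range <- species_length_range(range)
  }
  range <- .check_length_range(range)
  if (!is.na(k) && range[1] < k) {
    range[1] <- as.integer(k)  # cannot trim reads shorter than k
  }
  sized <- filter_length(aligned, range)
  out <- if (is.na(k)) sized else trim_5prime_to(sized, k)
  report <- data.frame(
    stage = c("input", "adaptor_trim", "dedup", "align", "length_filter",
              "trim_3prime_anchor"),
    reads = c(nrow(raw), nrow(trimmed), nrow(uniq), nrow(aligned),
              nrow(sized), nrow(out)))
  list(reads = out, range = range, report = report)
}
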