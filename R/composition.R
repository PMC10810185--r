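BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(outer(BASES, BASES, paste0))

#' Per-position nucleotide composition of fixed-length reads
#'
#' Counts each base at each 5'-anchored position across reads of a single
#' length (one panel per length, as plotted for the 12 lengths in the generic
#' 19-30 window). Reads containing N are excluded and counted.
#'
#' @param reads aligned-read/raw-read data.frame or character vector of
#'   sequences, all the same length.
#' @return a `position_composition` list: `counts` and `frequencies` (4 x L
#'   matrices, columns are 5' positions 1..L), `read_length`, `n_reads`,
#'   `n_excluded`.
#' @export
nucleotide_matrix <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  L <- unique(nchar(seqs))
  if (length(L) > 1) {
    stop("mixed read lengths (", paste(sort(L), collapse = ", "),
         "); compute one matrix per length")
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  seqs <- seqs[!has_n]
  counts <- matrix(0L, 4, L, dimnames = list(BASES, seq_len(L)))
  if (length(seqs) > 0) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    ncol = L, byrow = TRUE)
    for (j in seq_len(L)) {
      tab <- table(factor(chars[, j], levels = BASES))
      counts[, j] <- as.integer(tab)
    }
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1), "/")
  structure(list(counts = counts, frequencies = freq, read_length = L,
                 n_reads = length(seqs), n_excluded = sum(has_n)),
            class = "position_composition")
}

.dinuc_profile_one <- function(seqs, k) {
  has_n <- grepl("N", seqs, fixed = TRUE)
  seqs <- seqs[!has_n]
  counts <- matrix(0L, 16, k - 1,
                   dimnames = list(DINUCS, seq_len(k - 1)))
  for (i in seq_len(k - 1)) {
    tab <- table(factor(substring(seqs, i, i + 1), levels = DINUCS))
    counts[, i] <- as.integer(tab)
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1), "/")
  pyr <- data.frame(pos5 = seq_len(k - 1), offset3 = k - seq_len(k - 1),
                    frequency = colSums(freq[PYRIMIDINE_PAIRS, , drop = FALSE]))
  list(counts = counts, frequencies = freq, pyrimidine = pyr,
       n_reads = length(seqs), n_excluded = sum(has_n))
}

#' Per-position dinucleotide profiles, nuclear vs mitochondrial
#'
#' Splits trimmed reads by compartment (mitochondrial contig names are
#' configurable) and tabulates all 16 adjacent dinucleotides at every position
#' of the common-length reads, plus the aggregate pyrimidine-dinucleotide
#' frequency (TT+TC+CT+CC) per position. Mitochondrial reads are the internal
#' specificity control: genuine excised oligos show a pyrimidine-pair peak
#' whose 3'-most base sits at 3'-offsets 5-6, mitochondrial background does
#' not.
#'
#' Positions are reported both 5'-anchored (`pos5`, 1..k-1, the position of
#' the pair's first base) and as 3'-offsets (`offset3 = k - pos5`, the offset
#' of the pair's 3'-most base). Because [trim_5prime_to()] anchors reads at
#' the 3' end, `offset3` is comparable across original read lengths.
#'
#' @param reads aligned-read data.frame trimmed to a common length (see
#'   [trim_5prime_to()]).
#' @param mito_contigs contig names treated as mitochondrial.
#' @return a `dinucleotide_profile` list with elements `nuclear` and
#'   `mitochondrial` (each `counts`, `frequencies`, `pyrimidine`, `n_reads`,
#'   `n_excluded`; `NULL` when the compartment is empty) and `k`.
#' @export
dinucleotide_profile <- function(reads,
                                 mito_contigs = c("chrM", "MT", "M",
                                                  "mtDNA")) {
  k <- unique(nchar(reads$sequence))
  if (length(k) != 1) {
    stop("reads must be trimmed to a common length before profiling")
  }
  is_mito <- reads$contig %in% mito_contigs
  structure(list(
    nuclear = if (any(!is_mito)) {
      .dinuc_profile_one(reads$sequence[!is_mito], k)
    },
    mitochondrial = if (any(is_mito)) {
      .dinuc_profile_one(reads$sequence[is_mito], k)
    },
    k = k), class = "dinucleotide_profile")
}

#' Write a dinucleotide profile compartment as TSV
#'
#' One row per position: `pos5`, `offset3`, the 16 dinucleotide frequencies
#' and the aggregate pyrimidine-pair frequency.
#'
#' @param compartment one element (`$nuclear` or `$mitochondrial`) of a
#'   [dinucleotide_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dinucleotide_tsv <- function(compartment, path) {
  df <- cbind(compartment$pyrimidine[, c("pos5", "offset3")],
              as.data.frame(t(compartment$frequencies)),
              pyrimidine_pair = compartment$pyrimidine$frequency)
  write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
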