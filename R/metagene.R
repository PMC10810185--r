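#' Species gene-selection presets
#'
#' Minimum gene length and minimum distance to the nearest gene used for the
#' unit-gene analysis: human 5 kb / 5 kb, worm 1 kb / 500 bp, fly
#' 1 kb / 100 bp.
#'
#' @param species `"human"`, `"worm"` or `"fly"`.
#' @return list with `min_length`, `min_distance`.
#' @export
gene_selection_params <- function(species = c("human", "worm", "fly")) {
  species <- match.arg(species)
  switch(species,
         human = list(min_length = 5000L, min_distance = 5000L),
         worm = list(min_length = 1000L, min_distance = 500L),
         fly = list(min_length = 1000L, min_distance = 100L))
}

#' Select genes for the unit-gene analysis
#'
#' Keeps genes at least `min_length` long whose edge-to-edge, strand-ignorant
#' distance to the nearest other gene on the same contig is at least
#' `min_distance` (overlapping genes have distance 0). Genes whose 2 kb flanks
#' would run past a contig edge are kept but flagged `flank_truncated` when
#' contig lengths are supplied.
#'
#' @param genes gene-model data.frame.
#' @param min_length minimum gene length in bp.
#' @param min_distance minimum distance to the nearest gene in bp.
#' @param contig_lengths optional named vector of contig lengths (for the
#'   truncation flag).
#' @param flank flank size used by the binning scheme (bp).
#' @return filtered gene-model data.frame with a `flank_truncated` column.
#' @export
select_genes <- function(genes, min_length = 5000L, min_distance = 5000L,
                         contig_lengths = NULL, flank = 2000L) {
  len_ok <- genes$end - genes$start >= min_length
  dist <- rep(Inf, nrow(genes))
  for (ctg in unique(genes$contig)) {
    ii <- which(genes$contig == ctg)
    if (length(ii) < 2) next
    ord <- ii[order(genes$start[ii], genes$end[ii])]
    s <- genes$start[ord]; e <- genes$end[ord]
    gap_prev <- c(Inf, pmax(s[-1] - cummax(e[-length(e)]), 0))
    # distance to the nearest later-starting gene, scanning forward
    gap_next <- rep(Inf, length(ord))
    for (j in seq_len(length(ord) - 1)) {
      gap_next[j] <- max(s[j + 1] - e[j], 0)
    }
    dist[ord] <- pmin(gap_prev, gap_next)
  }
  out <- genes[len_ok & dist >= min_distance, ]
  rownames(out) <- NULL
  out$flank_truncated <- if (!is.null(contig_lengths)) {
    out$start < flank | out$end + flank > unname(contig_lengths[out$contig])
  } else rep(FALSE, nrow(out))
  out
}

#' Partition a gene into the 150-bin unit-gene scheme
#'
#' 25 upstream bins of 80 bp (2 kb), 100 body bins partitioning the gene into
#' near-equal parts (the remainder `r = length %% 100` is spread over the last
#' `r` body bins, which each get one extra base), and 25 downstream bins of
#' 80 bp. Bin 1 is always the bin 2 kb upstream of the transcription start
#' site, regardless of genomic strand, so bin order is 5'->3' of the gene.
#' Flank bins running past a contig edge are clipped (possibly to zero width).
#'
#' @param gene one-row gene-model data.frame (or list) with `gene_id`,
#'   `contig`, `start`, `end`, `strand`.
#' @param contig_length optional contig length for right-edge clipping.
#' @return data.frame of 150 rows: `gene_id`, `bin`, `region`, `contig`,
#'   `start`, `end`, `width`, `gene_strand`.
#' @export
bin_gene <- function(gene, contig_length = NULL) {
  L <- gene$end - gene$start
  if (L < 100) stop("gene ", gene$gene_id, " shorter than 100 bp")
  base <- L %/% 100L
  r <- L %% 100L
  w <- c(rep(base, 100 - r), rep(base + 1L, r))  # 5'->3' body widths
  if (gene$strand == "+") {
    up_start <- gene$start - 2000L + 80L * (0:24)
    body_end <- gene$start + cumsum(w)
    body_start <- body_end - w
    down_start <- gene$end + 80L * (0:24)
    start <- c(up_start, body_start, down_start)
    end <- c(up_start + 80L, body_end, down_start + 80L)
  } else {
    up_start <- gene$end + 80L * (24:0)
    body_end <- gene$end - cumsum(c(0L, w[-100]))
    body_start <- body_end - w
    down_end <- gene$start - 80L * (0:24)
    start <- c(up_start, body_start, down_end - 80L)
    end <- c(up_start + 80L, body_end, down_end)
  }
  if (!is.null(contig_length)) {
    start <- pmin(start, contig_length)
    end <- pmin(end, contig_length)
  }
  start <- pmax(start, 0L)
  end <- pmax(end, 0L)
  data.frame(gene_id = gene$gene_id, bin = 1:150,
             region = rep(c("upstream", "body", "downstream"), c(25, 100, 25)),
             contig = gene$contig, start = as.integer(start),
             end = as.integer(end), width = as.integer(end - start),
             gene_strand = gene$strand)
}

#' Bin every gene in a table
#'
#' @param genes gene-model data.frame.
#' @param contig_lengths optional named vector of contig lengths.
#' @return row-bound [bin_gene()] output, ordered by gene then bin.
#' @export
bin_genes <- function(genes, contig_lengths = NULL) {
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    bin_gene(genes[i, ],
             if (!is.null(contig_lengths)) {
               contig_lengths[[genes$contig[i]]]
             })
  }))
}

#' Count reads per gene bin, split by transcribed/non-transcribed strand
#'
#' A read is counted in a bin when their overlap covers at least
#' `min_overlap_fraction` of the read (the bedtools `-F 0.5` convention), so a
#' read can satisfy the criterion in at most `floor(1/f)` bins. Reads on the
#' strand *opposite* the gene's annotated strand are transcribed-strand (TS)
#' repair events -- the excised oligo is the strand being repaired -- and
#' same-strand reads are non-transcribed strand (NTS), mirroring bedtools
#' `-S` / `-s`.
#'
#' @param reads aligned-read data.frame.
#' @param bins output of [bin_genes()].
#' @param min_overlap_fraction minimum overlap as a fraction of read length.
#' @return list with `ts` and `nts` (genes x 150 count matrices), `width`
#'   (bin-width matrix) and `gene_ids`.
#' @export
assign_reads <- function(reads, bins, min_overlap_fraction = 0.5) {
  gene_ids <- unique(bins$gene_id)
  ng <- length(gene_ids)
  ts <- nts <- matrix(0L, ng, 150, dimnames = list(gene_ids, 1:150))
  wmat <- matrix(bins$width, ng, 150, byrow = TRUE,
                 dimnames = list(gene_ids, 1:150))
  if (nrow(reads) > 0 && nrow(bins) > 0) {
    nonempty <- which(bins$width > 0)
    bin_gr <- GenomicRanges::GRanges(
      bins$contig[nonempty],
      IRanges::IRanges(bins$start[nonempty] + 1, bins$end[nonempty]))
    read_gr <- GenomicRanges::GRanges(
      reads$contig, IRanges::IRanges(reads$start + 1, reads$end))
    ov <- GenomicRanges::findOverlaps(read_gr, bin_gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    ow <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(read_gr)[q], IRanges::ranges(bin_gr)[s]))
    rw <- reads$end[q] - reads$start[q]
    keep <- ow >= min_overlap_fraction * rw - 1e-9
    q <- q[keep]; s <- nonempty[s[keep]]
    is_ts <- reads$strand[q] != bins$gene_strand[s]
    gi <- match(bins$gene_id[s], gene_ids)
    flat <- (gi - 1L) * 150L + bins$bin[s]
    tts <- tabulate(flat[is_ts], nbins = ng * 150L)
    tnts <- tabulate(flat[!is_ts], nbins = ng * 150L)
    ts <- matrix(tts, ng, 150, byrow = TRUE, dimnames = list(gene_ids, 1:150))
    nts <- matrix(tnts, ng, 150, byrow = TRUE,
                  dimnames = list(gene_ids, 1:150))
  }
  list(ts = ts, nts = nts, width = wmat, gene_ids = gene_ids)
}

#' Rank genes by the TS/NTS read-number ratio
#'
#' Computes, on a reference (wild-type) sample, the per-gene ratio
#' `(TS + 1) / (NTS + 1)` (pseudocount guards empty genes), sorts descending
#' with ties broken by total reads then gene id, and returns the top `n`
#' genes.
#'
#' @param counts output of [assign_reads()] for the reference sample.
#' @param n number of genes to keep (the analysis uses 5000 on real
#'   annotations).
#' @return character vector of gene ids.
#' @export
rank_genes_ts_nts <- function(counts, n = 5000L) {
  ts <- rowSums(counts$ts)
  nts <- rowSums(counts$nts)
  ratio <- (ts + 1) / (nts + 1)
  ord <- order(-ratio, -(ts + nts), counts$gene_ids)
  counts$gene_ids[head(ord, min(n, length(ord)))]
}

#' Average per-bin RPKM profile over selected genes
#'
#' For each gene, bin and strand, computes reads per kilobase of bin per
#' million total reads: `count / (width_kb * total/1e6)`; the profile is the
#' mean over genes. `total_mapped_reads` should be the sample's full count of
#' genome-aligned, length- and damage-filtered reads. Zero-width (clipped)
#' bins are excluded from the mean.
#'
#' @param counts output of [assign_reads()].
#' @param total_mapped_reads total filtered reads in the sample.
#' @param genes optional character vector restricting the average to a gene
#'   subset (e.g. from [rank_genes_ts_nts()]).
#' @return a `unit_gene_profile` data.frame with columns `bin`, `region`,
#'   `TS`, `NTS`; `attr(, "n_genes")` records the genes averaged.
#' @export
profile_rpkm <- function(counts, total_mapped_reads, genes = NULL) {
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  sel <- if (is.null(genes)) counts$gene_ids else genes
  ii <- match(sel, counts$gene_ids)
  if (anyNA(ii)) stop("unknown gene id(s) in `genes`")
  scale <- (counts$width[ii, , drop = FALSE] / 1000) *
    (total_mapped_reads / 1e6)
  scale[scale == 0] <- NA
  ts <- counts$ts[ii, , drop = FALSE] / scale
  nts <- counts$nts[ii, , drop = FALSE] / scale
  out <- data.frame(bin = 1:150,
                    region = rep(c("upstream", "body", "downstream"),
                                 c(25, 100, 25)),
                    TS = colMeans(ts, na.rm = TRUE),
                    NTS = colMeans(nts, na.rm = TRUE))
  out$TS[is.nan(out$TS)] <- 0
  out$NTS[is.nan(out$NTS)] <- 0
  rownames(out) <- NULL
  attr(out, "n_genes") <- length(sel)
  class(out) <- c("unit_gene_profile", "data.frame")
  out
}

#' Full unit-gene metagene profile
#'
#' Convenience wrapper: select genes, bin them, assign reads, rank genes by
#' the reference TS/NTS ratio and average RPKM over the top genes.
#'
#' @param reads filtered aligned reads of the sample to profile.
#' @param genes gene-model data.frame.
#' @param min_length,min_distance gene-selection thresholds (see
#'   [gene_selection_params()]).
#' @param contig_lengths optional named vector of contig lengths.
#' @param top_n genes kept after ranking.
#' @param total_mapped_reads total filtered reads (defaults to `nrow(reads)`).
#' @param reference_counts optional [assign_reads()] output from the wild-type
#'   sample used for ranking; defaults to this sample's own counts.
#' @return list with `profile`, `selected_genes`, `top_genes`, `counts`.
#' @export
metagene_profile <- function(reads, genes, min_length = 5000L,
                             min_distance = 5000L, contig_lengths = NULL,
                             top_n = 5000L,
                             total_mapped_reads = nrow(reads),
                             reference_counts = NULL) {
  sel <- select_genes(genes, min_length, min_distance, contig_lengths)
  if (nrow(sel) == 0) stop("no genes pass the selection thresholds")
  bins <- bin_genes(sel, contig_lengths)
  counts <- assign_reads(reads, bins)
  top <- rank_genes_ts_nts(
    if (is.null(reference_counts)) counts else reference_counts, top_n)
  top <- intersect(top, counts$gene_ids)
  prof <- profile_rpkm(counts, total_mapped_reads, top)
  list(profile = prof, selected_genes = sel, top_genes = top, counts = counts)
}
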