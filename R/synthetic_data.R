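#' Parameters for the synthetic qXR-Seq experiment generator
#'
#' Bundles and validates everything the generator needs to emulate an
#' excised-oligo library: a small genome with a mitochondrial contig, gene
#' models, reads of 19-30 nt whose 3' ends carry a dipyrimidine at the
#' position the dual incision places the lesion (3'-offsets 5-6), a
#' programmable transcribed-strand bias within genes, signature-free
#' mitochondrial background, adaptor-bearing duplicated raw reads, and a
#' wild-type dilution series with a constant spike-in.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param genome_sizes named integer vector of contig sizes in bp. Must
#'   include a contig named `chrM` whenever `mito_fraction > 0`.
#' @param gc genome GC content in (0,1).
#' @param n_genes number of gene models to place.
#' @param gene_length_range length 2 vector, gene lengths drawn uniformly.
#' @param intergenic_gap minimum gap between neighbouring genes in bp (actual
#'   gaps drawn uniformly in `[gap, 3*gap]` so gene-selection thresholds see
#'   both outcomes).
#' @param n_reads number of library molecules to emit.
#' @param length_weights named numeric vector over lengths 19..30 summing to
#'   1; default uniform. The real length distribution is species-specific and
#'   not published, hence the uniform default.
#' @param signal_fraction fraction of nuclear reads that carry the damage
#'   signature (placed inside genes with the transcribed-strand bias).
#' @param damage_offset_weights named weights over 3'-offsets of the
#'   dipyrimidine's 3'-most base; key `o` places the two pyrimidines at
#'   3'-offsets `o` and `o+1`. Default `c("5" = 0.5, "6" = 0.5)`, the
#'   canonical excision-repair placement.
#' @param tcr_ratio odds that a signal read comes from the transcribed strand
#'   (maps antisense to its gene) rather than the non-transcribed strand;
#'   `>= 1`.
#' @param mito_fraction fraction of reads originating on `chrM`; these are
#'   always signature-free background (the assay-specificity control).
#' @param spike_reads number of spike-in reads added to every member of a
#'   dilution series.
#' @param adaptor 3' sequencing adaptor appended to every raw read.
#' @param duplicate_rate probability that a raw read is emitted twice (library
#'   PCR duplication).
#' @param dilutions dilution fractions of the wild-type series, each in (0,1].
#' @return a validated `simulation_params` list.
#' @export
simulation_params <- function(seed = 1L,
                              genome_sizes = c(chr1 = 200000L, chrM = 16000L),
                              gc = 0.5,
                              n_genes = 30L,
                              gene_length_range = c(1000L, 6000L),
                              intergenic_gap = 300L,
                              n_reads = 20000L,
                              length_weights = NULL,
                              signal_fraction = 0.9,
                              damage_offset_weights = c("5" = 0.5, "6" = 0.5),
                              tcr_ratio = 4,
                              mito_fraction = 0.05,
                              spike_reads = 2000L,
                              adaptor = "TGGAATTCTCGGGTGCCAAGG",
                              duplicate_rate = 0.2,
                              dilutions = c(1, 0.1, 0.01, 0.001, 1e-4)) {
  if (is.null(length_weights)) {
    length_weights <- setNames(rep(1 / 12, 12), 19:30)
  }
  stopifnot(length(seed) == 1, is.finite(seed))
  if (any(genome_sizes < 1000)) {
    stop("every contig must be at least 1 kb; got ",
         paste(genome_sizes[genome_sizes < 1000], collapse = ", "))
  }
  if (mito_fraction > 0 && !"chrM" %in% names(genome_sizes)) {
    stop("genome_sizes must include a contig named 'chrM' when mito_fraction > 0")
  }
  lens <- as.integer(names(length_weights))
  if (anyNA(lens) || any(lens < 19 | lens > 30)) {
    stop("length_weights must be named by read lengths in 19..30")
  }
  offs <- as.integer(names(damage_offset_weights))
  if (anyNA(offs) || any(offs < 4 | offs > 9)) {
    stop("damage_offset_weights keys must be 3'-offsets in 4..9 so both bases
         of the dipyrimidine sit within the 4-10 window")
  }
  fracs <- c(signal_fraction, mito_fraction, duplicate_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(length_weights) - 1) > 1e-8) stop("length_weights must sum to 1")
  if (abs(sum(damage_offset_weights) - 1) > 1e-8) {
    stop("damage_offset_weights must sum to 1")
  }
  if (tcr_ratio < 1) stop("tcr_ratio must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  if (any(dilutions <= 0 | dilutions > 1)) stop("dilutions must lie in (0, 1]")
  if (!grepl("^[ACGT]+$", adaptor)) stop("adaptor must be a DNA string")
  structure(list(seed = as.integer(seed), genome_sizes = genome_sizes, gc = gc,
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_gap = as.integer(intergenic_gap),
                 n_reads = as.integer(n_reads),
                 length_weights = length_weights,
                 signal_fraction = signal_fraction,
                 damage_offset_weights = damage_offset_weights,
                 tcr_ratio = tcr_ratio, mito_fraction = mito_fraction,
                 spike_reads = as.integer(spike_reads), adaptor = adaptor,
                 duplicate_rate = duplicate_rate, dilutions = dilutions),
            class = "simulation_params")
}

MITO_CONTIGS <- c("chrM", "MT", "M", "mtDNA")

#' Generate a random genome
#'
#' Deterministic given the seed: contig sequences are i.i.d. bases with the
#' requested GC content.
#'
#' @param params a [simulation_params()] object.
#' @return named character vector of contig sequences.
#' @export
make_genome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  p <- c((1 - params$gc) / 2, params$gc / 2, params$gc / 2, (1 - params$gc) / 2)
  vapply(params$genome_sizes, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

#' Place non-overlapping gene models on a genome
#'
#' Genes are packed left-to-right on the nuclear contigs with uniformly drawn
#' lengths and gaps (gaps in `[intergenic_gap, 3*intergenic_gap]`), strands
#' Bernoulli(0.5). No genes are placed on mitochondrial contigs.
#'
#' @param genome genome from [make_genome()] (or any named character vector).
#' @param params a [simulation_params()] object.
#' @return gene-model data.frame (`gene_id`, `contig`, `start`, `end`,
#'   `strand`).
#' @export
make_genes <- function(genome, params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed + 1L)
  nuclear <- setdiff(names(genome), MITO_CONTIGS)
  if (length(nuclear) == 0) stop("no nuclear contig to place genes on")
  n <- params$n_genes
  lens <- sample(seq(params$gene_length_range[1], params$gene_length_range[2]),
                 n, replace = TRUE)
  gaps <- sample(seq(params$intergenic_gap, 3 * params$intergenic_gap),
                 n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  contig <- character(n); start <- integer(n)
  ci <- 1L
  pos <- gaps[1]
  for (i in seq_len(n)) {
    while (pos + lens[i] > nchar(genome[[nuclear[ci]]])) {
      ci <- ci + 1L
      if (ci > length(nuclear)) {
        stop("infeasible packing: cannot place ", n, " genes of the requested",
             " size in the nuclear contigs")
      }
      pos <- gaps[i]
    }
    contig[i] <- nuclear[ci]
    start[i] <- pos
    pos <- pos + lens[i] + gaps[i]
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), contig = contig,
             start = start, end = start + lens, strand = strands)
}

.extract_read_seq <- function(genome, contig, start, end, strand) {
  s <- substring(genome[contig], start + 1, end)
  neg <- strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  unname(s)
}

# Vectorised rejection sampling: draw start positions inside [lo, hi - L]
# until the read-oriented sequence carries a pyrimidine pair at 3'-offsets
# (o, o+1), i.e. 5' positions (L - o, L - o + 1).
.place_signal <- function(genome, contig, lo, hi, strand, L, o,
                          max_iter = 500L) {
  n <- length(contig)
  start <- integer(n); seq <- character(n)
  todo <- seq_len(n)
  for (it in seq_len(max_iter)) {
    if (length(todo) == 0) break
    cand <- lo[todo] + floor(runif(length(todo)) *
                               (hi[todo] - lo[todo] - L[todo] + 1))
    s <- .extract_read_seq(genome, contig[todo], cand, cand + L[todo],
                           strand[todo])
    ok <- substring(s, L[todo] - o[todo], L[todo] - o[todo] + 1) %in%
      PYRIMIDINE_PAIRS & !grepl("N", s, fixed = TRUE)
    start[todo[ok]] <- cand[ok]
    seq[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  if (length(todo) > 0) {
    stop("could not place a dipyrimidine-bearing read after ", max_iter,
         " attempts; genome region too pyrimidine-poor")
  }
  list(start = start, sequence = seq)
}

#' Simulate an excised-oligo library with ground truth
#'
#' Emits one record per library molecule: signal reads are placed inside genes
#' so that the reference sequence itself carries a pyrimidine dinucleotide at
#' the drawn 3'-offset (site-directed rejection sampling; the genome is never
#' mutated, so exact alignment recovers every read), with strand odds
#' `tcr_ratio` favouring the transcribed strand (read antisense to the gene).
#' Background reads are uniform over the compartment; mitochondrial reads are
#' always background. Raw reads are the molecule sequences with the adaptor
#' appended, duplicated at `duplicate_rate`.
#'
#' @param genome genome from [make_genome()].
#' @param genes gene models from [make_genes()]; may be `NULL` for a library
#'   with no annotated genes (signal reads are then placed anywhere on the
#'   nuclear contigs).
#' @param params a [simulation_params()] object.
#' @param sample_id sample label.
#' @param species species tag carried by every read.
#' @param id_prefix prefix for read ids (keeps ids unique when libraries are
#'   mixed).
#' @param seed random seed; defaults to `params$seed + 2`.
#' @return an `xr_library`: list with `reads` (aligned-read data.frame with a
#'   `species` column), `raw` (adaptor-bearing, duplicated raw reads),
#'   `manifest` (one truth row per molecule: origin, strand class, signal
#'   flag, damage offset), `sample_id`, `species`.
#' @export
simulate_library <- function(genome, genes, params, sample_id = "WT",
                             species = "sample", id_prefix = "r",
                             seed = params$seed + 2L) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  n <- params$n_reads
  lens <- as.integer(names(params$length_weights))
  L <- lens[sample.int(length(lens), n, replace = TRUE,
                       prob = params$length_weights)]
  mito <- intersect(names(genome), MITO_CONTIGS)
  is_mito <- if (length(mito) > 0 && params$mito_fraction > 0) {
    runif(n) < params$mito_fraction
  } else rep(FALSE, n)
  has_genes <- !is.null(genes) && nrow(genes) > 0
  is_signal <- !is_mito & runif(n) < params$signal_fraction

  contig <- character(n); start <- integer(n); strand <- character(n)
  seqs <- character(n)
  origin <- rep("intergenic", n)
  strand_class <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)

  nuclear <- setdiff(names(genome), MITO_CONTIGS)
  nuc_len <- nchar(genome[nuclear])

  # signal reads: inside a gene (or anywhere nuclear when no genes given),
  # strand odds tcr_ratio for the transcribed strand
  si <- which(is_signal)
  if (length(si) > 0) {
    offs <- as.integer(names(params$damage_offset_weights))
    o <- offs[sample.int(length(offs), length(si), replace = TRUE,
                         prob = params$damage_offset_weights)]
    offset[si] <- o
    if (has_genes) {
      gi <- sample(nrow(genes), length(si), replace = TRUE)
      p_ts <- params$tcr_ratio / (1 + params$tcr_ratio)
      on_ts <- runif(length(si)) < p_ts
      gs <- genes$strand[gi]
      rs <- ifelse(on_ts, ifelse(gs == "+", "-", "+"), gs)
      placed <- .place_signal(genome, genes$contig[gi], genes$start[gi],
                              genes$end[gi], rs, L[si], o)
      contig[si] <- genes$contig[gi]
      strand[si] <- rs
      origin[si] <- genes$gene_id[gi]
      strand_class[si] <- ifelse(on_ts, "TS", "NTS")
    } else {
      ci <- sample(nuclear, length(si), replace = TRUE, prob = nuc_len)
      rs <- sample(c("+", "-"), length(si), replace = TRUE)
      placed <- .place_signal(genome, ci, rep(0L, length(si)),
                              nchar(genome[ci]), rs, L[si], o)
      contig[si] <- ci
      strand[si] <- rs
    }
    start[si] <- placed$start
    seqs[si] <- placed$sequence
  }

  # background reads: uniform positions, uniform strand, no placement rule
  bg <- which(!is_signal)
  if (length(bg) > 0) {
    bg_mito <- bg[is_mito[bg]]
    bg_nuc <- bg[!is_mito[bg]]
    if (length(bg_nuc) > 0) {
      ci <- sample(nuclear, length(bg_nuc), replace = TRUE, prob = nuc_len)
      contig[bg_nuc] <- ci
    }
    if (length(bg_mito) > 0) {
      contig[bg_mito] <- sample(mito, length(bg_mito), replace = TRUE)
      origin[bg_mito] <- "chrM"
    }
    clen <- nchar(genome[contig[bg]])
    start[bg] <- floor(runif(length(bg)) * (clen - L[bg] + 1))
    strand[bg] <- sample(c("+", "-"), length(bg), replace = TRUE)
    seqs[bg] <- .extract_read_seq(genome, contig[bg], start[bg],
                                  start[bg] + L[bg], strand[bg])
    # truth origin for nuclear background reads fully inside a gene
    if (has_genes && length(bg_nuc) > 0) {
      for (g in seq_len(nrow(genes))) {
        inside <- contig[bg_nuc] == genes$contig[g] &
          start[bg_nuc] >= genes$start[g] &
          start[bg_nuc] + L[bg_nuc] <= genes$end[g]
        if (any(inside)) {
          idx <- bg_nuc[inside]
          origin[idx] <- genes$gene_id[g]
          strand_class[idx] <- ifelse(strand[idx] == genes$strand[g],
                                      "NTS", "TS")
        }
      }
    }
  }

  read_id <- sprintf("%s%06d", id_prefix, seq_len(n))
  reads <- aligned_reads(read_id, contig, start, start + L, strand, seqs,
                         sample_id)
  reads$species <- species
  manifest <- data.frame(read_id = read_id, contig = contig, start = start,
                         end = start + L, strand = strand, length = L,
                         origin = origin, strand_class = strand_class,
                         signal = is_signal, damage_offset = offset,
                         sequence = seqs)

  dup <- runif(n) < params$duplicate_rate
  raw <- raw_reads(c(read_id, paste0(read_id[dup], "_dup")),
                   paste0(c(seqs, seqs[dup]), params$adaptor))

  structure(list(reads = reads, raw = raw, manifest = manifest,
                 sample_id = sample_id, species = species,
                 dilution = NA_real_),
            class = "xr_library")
}

#' Build a wild-type dilution series with a constant spike-in
#'
#' Each series member retains every base-library molecule independently with
#' probability `d` (binomial thinning, the statistical analogue of a serial
#' dilution) and receives exactly `spike_reads` molecules sampled without
#' replacement from the spike library. Raw reads and manifests are subset
#' consistently; the true dilution is recorded per member.
#'
#' @param base an `xr_library` (the wild-type sample).
#' @param spike an `xr_library` from the spike-in species (use a distinct
#'   `id_prefix` so read ids do not collide).
#' @param dilutions numeric vector of fractions in (0,1].
#' @param spike_reads spike molecules added to every member.
#' @param seed random seed.
#' @return list of `xr_library` objects, one per dilution, each with
#'   `$dilution` set.
#' @export
make_spikein_series <- function(base, spike, dilutions = base$dilutions,
                                spike_reads, seed = 100L) {
  stopifnot(inherits(base, "xr_library"), inherits(spike, "xr_library"))
  if (nrow(base$reads) == 0) stop("empty base library")
  if (any(dilutions <= 0 | dilutions > 1)) stop("dilutions must be in (0, 1]")
  if (spike_reads > nrow(spike$reads)) {
    stop("spike library has only ", nrow(spike$reads), " reads; ",
         spike_reads, " requested")
  }
  lapply(seq_along(dilutions), function(i) {
    d <- dilutions[i]
    set.seed(seed + i)
    keep <- runif(nrow(base$reads)) < d
    sel <- sample(nrow(spike$reads), spike_reads)
    ids <- c(base$reads$read_id[keep], spike$reads$read_id[sel])
    sample_id <- sprintf("%s_dil%g", base$sample_id, d)
    reads <- rbind(base$reads[keep, ], spike$reads[sel, ])
    reads$sample_id <- sample_id
    raw <- rbind(base$raw, spike$raw)
    raw <- raw[sub("_dup$", "", raw$read_id) %in% ids, ]
    manifest <- rbind(cbind(base$manifest[keep, ], species = base$species),
                      cbind(spike$manifest[sel, ], species = spike$species))
    rownames(reads) <- rownames(raw) <- rownames(manifest) <- NULL
    structure(list(reads = reads, raw = raw, manifest = manifest,
                   sample_id = sample_id, species = base$species,
                   spike_species = spike$species, dilution = d),
              class = "xr_library")
  })
}
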