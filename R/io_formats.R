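#' @importFrom utils head read.delim write.table
#' @importFrom stats setNames
NULL

PYRIMIDINE_PAIRS <- c("CC", "CT", "TC", "TT")

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement built on Biostrings. Used everywhere a read
#' sequence has to be converted between read orientation (5'->3' of the excised
#' oligo) and the reference plus strand.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)),
               use.names = FALSE)
}

#' Read a FASTA file with strict validation
#'
#' A validating FASTA reader: it enforces unique record ids, non-empty
#' sequences, and a legal alphabet, reporting the offending line number on
#' failure. Sequences are uppercased. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"DNA"` (A/C/G/T/N) or `"AA"` (amino acids, `*` and the gap
#'   character `-` allowed, for alignments).
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) return(setNames(character(0), character(0)))
  if (!is_hdr[nonblank[1]]) {
    stop("malformed FASTA at line ", nonblank[1], ": sequence before header")
  }
  ids <- vapply(strsplit(sub("^>\\s*", "", lines[is_hdr]), "\\s+"),
                `[`, character(1), 1L)
  if (anyNA(ids) || any(ids == "")) {
    bad <- which(is_hdr)[which(is.na(ids) | ids == "")[1]]
    stop("malformed FASTA at line ", bad, ": empty header")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pattern <- if (alphabet == "DNA") "^[ACGTN]*$" else "^[A-Z*.-]*$"
  seq_lines <- toupper(ifelse(is_hdr, "", gsub("\\s", "", lines)))
  bad <- which(!grepl(pattern, seq_lines))
  if (length(bad) > 0) {
    stop("illegal ", alphabet, " character in FASTA at line ", bad[1])
  }
  grp <- cumsum(is_hdr)
  keep <- !is_hdr & seq_lines != ""
  seqs <- vapply(seq_along(ids), function(i) {
    paste(seq_lines[keep & grp == i], collapse = "")
  }, character(1))
  if (any(seqs == "")) {
    stop("empty sequence for FASTA record(s): ",
         paste(ids[seqs == ""], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read raw reads from FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the raw-read
#' table used by the processing stage. Quality strings are discarded (the
#' pipeline performs no quality trimming).
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate read ids in FASTQ: ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  raw_reads(ids, toupper(as.character(x)))
}

#' Construct a raw-read table
#'
#' @param read_id character vector of unique read ids.
#' @param sequence character vector of read sequences (read orientation).
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
raw_reads <- function(read_id, sequence) {
  stopifnot(length(read_id) == length(sequence))
  if (any(nchar(sequence) == 0)) stop("raw reads must have non-empty sequences")
  data.frame(read_id = as.character(read_id),
             sequence = toupper(as.character(sequence)))
}

.read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop("BED6 format error at line ", which(nf < 6)[1],
         ": expected >= 6 tab-separated columns, got ", nf[nf < 6][1])
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("BED6 format error at line ", bad[1], ": non-integer coordinates")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("BED6 format error at line ", bad[1],
         ": require 0 <= start < end, got [", start[bad[1]], ", ",
         end[bad[1]], ")")
  }
  bad <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad) > 0) {
    stop("BED6 format error at line ", bad[1], ": unknown strand symbol '",
         m[bad[1], 6], "'")
  }
  data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
             score = suppressWarnings(as.numeric(m[, 5])), strand = m[, 6])
}

#' Read aligned reads from a BED6 file
#'
#' Ingestion point for externally aligned data. Coordinates are 0-based
#' half-open (BED convention). The stored sequence is always read-oriented
#' (5'->3' of the excised oligo): on the minus strand it is the reverse
#' complement of the reference slice.
#'
#' @param path path to a BED6 file (`chrom start end name score strand`).
#' @param sequences optional named character vector of read sequences (e.g.
#'   from [read_fasta()]); row names must match BED `name` entries.
#' @param genome optional genome (named character vector of contig sequences)
#'   used to reconstruct read sequences when `sequences` is not given.
#' @param sample_id sample label attached to every read.
#' @return an aligned-read data.frame with columns `read_id`, `contig`,
#'   `start`, `end`, `strand`, `sequence`, `sample_id`.
#' @export
read_bed6_reads <- function(path, sequences = NULL, genome = NULL,
                            sample_id = "sample") {
  bed <- .read_bed6(path)
  if (nrow(bed) == 0) {
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0), character(0), sample_id))
  }
  if (!is.null(sequences)) {
    miss <- which(!bed$name %in% names(sequences))
    if (length(miss) > 0) {
      stop("BED6 row ", miss[1], ": no sequence for read id '",
           bed$name[miss[1]], "'")
    }
    seq <- unname(sequences[bed$name])
    bad <- which(nchar(seq) != bed$end - bed$start)
    if (length(bad) > 0) {
      stop("BED6 row ", bad[1], ": sequence length ", nchar(seq[bad[1]]),
           " does not match interval width ",
           bed$end[bad[1]] - bed$start[bad[1]])
    }
  } else if (!is.null(genome)) {
    miss <- which(!bed$chrom %in% names(genome))
    if (length(miss) > 0) {
      stop("BED6 row ", miss[1], ": unknown contig '", bed$chrom[miss[1]], "'")
    }
    too_far <- which(bed$end > nchar(genome[bed$chrom]))
    if (length(too_far) > 0) {
      stop("BED6 row ", too_far[1], ": interval beyond contig end")
    }
    seq <- substring(genome[bed$chrom], bed$start + 1, bed$end)
    neg <- bed$strand == "-"
    if (any(neg)) seq[neg] <- revcomp(seq[neg])
  } else {
    stop("missing sequence source: provide `sequences` or `genome`")
  }
  aligned_reads(bed$name, bed$chrom, bed$start, bed$end, bed$strand, seq,
                sample_id)
}

#' Construct an aligned-read table
#'
#' Invariants checked: `end - start == nchar(sequence)`, 0-based half-open
#' intervals, strand in `{+,-}`.
#'
#' @param read_id,contig,start,end,strand,sequence per-read vectors.
#' @param sample_id sample label (recycled).
#' @return data.frame of aligned reads.
#' @export
aligned_reads <- function(read_id, contig, start, end, strand, sequence,
                          sample_id = "sample") {
  df <- data.frame(read_id = as.character(read_id),
                   contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   sequence = toupper(as.character(sequence)),
                   sample_id = rep_len(sample_id, length(read_id)))
  if (nrow(df) > 0) {
    stopifnot(all(df$strand %in% c("+", "-")),
              all(df$start >= 0), all(df$end > df$start),
              all(df$end - df$start == nchar(df$sequence)))
  }
  df
}

#' Write aligned reads as BED6
#'
#' @param reads aligned-read data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6_reads <- function(reads, path) {
  df <- data.frame(reads$contig, reads$start, reads$end, reads$read_id,
                   0L, reads$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED6 file
#'
#' @param path path to a BED6 file; the `name` column is the gene id and must
#'   be unique.
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_bed6_genes <- function(path) {
  bed <- .read_bed6(path)
  if (anyDuplicated(bed$name)) {
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(bed$name[duplicated(bed$name)]), collapse = ", "))
  }
  data.frame(gene_id = bed$name, contig = bed$chrom, start = bed$start,
             end = bed$end, strand = bed$strand)
}

#' Write gene models as BED6
#'
#' @param genes gene-model data.frame (`gene_id`, `contig`, `start`, `end`,
#'   `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6_genes <- function(genes, path) {
  df <- data.frame(genes$contig, genes$start, genes$end, genes$gene_id,
                   0L, genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated table with one row per sequencing library. Required columns:
#' `sample_id`, `species`, `spike_species`, `uv` (logical), `genotype`;
#' optional: `dilution` (in (0,1], for calibration-series members) and
#' `input_scale` (starting material loaded relative to wild type, e.g. 2000
#' for low-repair mutant lines; default 1).
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "spike_species", "uv", "genotype")
  miss <- setdiff(need, names(ss))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  if (length(unique(ss$spike_species)) != 1) {
    stop("sample sheet must use exactly one spike_species per experiment")
  }
  ss$uv <- as.logical(ss$uv)
  if (is.null(ss$input_scale)) ss$input_scale <- 1
  ss$input_scale[is.na(ss$input_scale)] <- 1
  if (any(ss$input_scale <= 0)) stop("input_scale must be > 0")
  if (!is.null(ss$dilution)) {
    d <- ss$dilution[!is.na(ss$dilution)]
    if (any(d <= 0 | d > 1)) stop("dilution values must lie in (0, 1]")
  } else {
    ss$dilution <- NA_real_
  }
  ss
}

#' Write a metagene profile as TSV
#'
#' Writes the 150-bin profile (`bin`, `TS`, `NTS`) with full precision so a
#' write-then-read round trip reproduces values to better than 1e-9.
#'
#' @param profile data.frame with columns `bin`, `TS`, `NTS`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(all(c("bin", "TS", "NTS") %in% names(profile)))
  df <- profile[, c("bin", "TS", "NTS")]
  df$TS <- sprintf("%.12g", df$TS)
  df$NTS <- sprintf("%.12g", df$NTS)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a metagene profile TSV
#'
#' @param path path written by [write_profile_tsv()].
#' @return data.frame with columns `bin`, `TS`, `NTS`.
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bin", "TS", "NTS") %in% names(df)))
  df$TS <- as.numeric(df$TS)
  df$NTS <- as.numeric(df$NTS)
  df
}

#' Read a species-to-lineage map
#'
#' Two-column TSV: `species_id<TAB>taxon1;taxon2;...` with lineages ordered
#' root to species.
#'
#' @param path path to the TSV file.
#' @return named list of character vectors (one lineage per species).
#' @export
read_lineage_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("lineage TSV format error at line ", which(nf < 2)[1],
         ": expected species<TAB>taxa")
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate species ids in lineage map")
  lin <- lapply(fields, function(f) strsplit(f[2], ";", fixed = TRUE)[[1]])
  setNames(lin, ids)
}
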