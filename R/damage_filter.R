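#' Test for the excision-repair damage signature at the 3' end
#'
#' An excised oligo produced by the dual incision carries its lesion -- a
#' dipyrimidine, since both UV photoproducts form at adjacent pyrimidines --
#' a fixed distance from the 3' incision site. This predicate is true when two
#' adjacent bases, both C or T, sit with *both* members inside the 3'-offset
#' window (offset 1 = the 3'-terminal base; default window 4-10). Sequences
#' are read-oriented (5'->3' of the oligo) and the verdict depends only on the
#' last `window[2]` bases, so 5' trimming or extension never changes it.
#' Reads containing N are rejected.
#'
#' @param sequences character vector of read-oriented sequences, each at least
#'   `window[2]` nt long.
#' @param window integer `c(lo, hi)` of 1-based 3'-offsets; both bases of the
#'   dinucleotide must lie within it.
#' @return logical vector.
#' @export
has_dipyrimidine_3prime <- function(sequences, window = c(4L, 10L)) {
  stopifnot(length(window) == 2, window[1] >= 1, window[1] < window[2])
  L <- nchar(sequences)
  if (any(L < window[2])) {
    stop("sequence shorter than the 3'-offset window (need >= ", window[2],
         " nt)")
  }
  res <- rep(FALSE, length(sequences))
  # pair occupying offsets (p, p+1) sits at 5' positions (L - p, L - p + 1)
  for (p in seq(window[1], window[2] - 1L)) {
    res <- res | substring(sequences, L - p, L - p + 1) %in% PYRIMIDINE_PAIRS
  }
  res & !grepl("N", sequences, fixed = TRUE)
}

#' Keep only reads carrying the damage signature
#'
#' @param reads aligned-read (or raw-read) data.frame.
#' @param window 3'-offset window passed to [has_dipyrimidine_3prime()].
#' @return filtered data.frame; `attr(, "stats")` holds `c(kept, dropped)`.
#' @export
filter_damage <- function(reads, window = c(4L, 10L)) {
  if (nrow(reads) == 0) {
    out <- reads
    attr(out, "stats") <- c(kept = 0L, dropped = 0L)
    return(out)
  }
  keep <- has_dipyrimidine_3prime(reads$sequence, window)
  out <- reads[keep, ]
  rownames(out) <- NULL
  attr(out, "stats") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}
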