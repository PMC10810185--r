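#' Partition reads between the sample and spike-in species
#'
#' Aligns every read to both genomes and assigns it to the species where it
#' aligns exactly once while not aligning at all to the other. Reads hitting
#' both genomes (ambiguous), hitting neither, or multi-mapping within one
#' genome are dropped and counted -- a conservative rule that preserves the
#' ordering of sample:spike ratios.
#'
#' @param reads raw-read data.frame (post trimming/deduplication).
#' @param sample_genome,spike_genome named character vectors of contig
#'   sequences; must be labelled with distinct species names.
#' @param species,spike_species species labels for the two genomes.
#' @return list with `sample` and `spike` aligned-read data.frames (with a
#'   `species` column) and `counts`
#'   (`c(sample, spike, ambiguous, multimapped, unmapped)`).
#' @export
partition_by_species <- function(reads, sample_genome, spike_genome,
                                 species = "sample",
                                 spike_species = "spike") {
  if (identical(species, spike_species)) {
    stop("sample and spike species labels must differ")
  }
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  clean <- reads[!has_n, ]
  ha <- .exact_hits(clean$sequence, sample_genome)
  hb <- .exact_hits(clean$sequence, spike_genome)
  to_a <- ha$hits == 1 & hb$hits == 0
  to_b <- hb$hits == 1 & ha$hits == 0
  ambiguous <- ha$hits > 0 & hb$hits > 0
  multi <- (ha$hits > 1 & hb$hits == 0) | (hb$hits > 1 & ha$hits == 0)
  unmapped <- ha$hits == 0 & hb$hits == 0
  L <- nchar(clean$sequence)
  mk <- function(sel, h, label) {
    out <- aligned_reads(clean$read_id[sel], h$contig[sel], h$start[sel],
                         h$start[sel] + L[sel], h$strand[sel],
                         clean$sequence[sel], label)
    out$species <- label
    out
  }
  list(sample = mk(to_a, ha, species), spike = mk(to_b, hb, spike_species),
       counts = c(sample = sum(to_a), spike = sum(to_b),
                  ambiguous = sum(ambiguous), multimapped = sum(multi),
                  unmapped = sum(unmapped) + sum(has_n)))
}

#' Construct per-library read counts for quantification
#'
#' @param sample_id library label.
#' @param n_sample filtered reads mapped to the sample species.
#' @param n_spike filtered reads mapped to the spike-in species.
#' @param dilution dilution fraction for calibration-series members, else `NA`.
#' @param input_scale starting material loaded relative to wild type (e.g.
#'   2000 when 2000x more material was used for a repair-deficient line).
#' @return one-row data.frame.
#' @export
library_counts <- function(sample_id, n_sample, n_spike, dilution = NA_real_,
                           input_scale = 1) {
  stopifnot(n_sample >= 0, n_spike >= 0, input_scale > 0)
  data.frame(sample_id = sample_id, n_sample = n_sample, n_spike = n_spike,
             dilution = dilution, input_scale = input_scale)
}

#' Sample:spike read ratio
#'
#' The quantification currency of the spike-in design: because every library
#' received the same amount of spike-in material, `n_sample / n_spike` is
#' proportional to the amount of excised oligos in the sample, independent of
#' sequencing depth.
#'
#' @param counts data.frame with columns `n_sample`, `n_spike` (one or more
#'   rows).
#' @return numeric vector of ratios.
#' @export
ratio <- function(counts) {
  if (any(counts$n_spike == 0)) {
    stop("undefined ratio: n_spike is 0 for ",
         paste(counts$sample_id[counts$n_spike == 0], collapse = ", "))
  }
  counts$n_sample / counts$n_spike
}

#' Fit the wild-type dilution calibration line
#'
#' Least squares of the sample:spike ratio on the dilution fraction. The
#' default is regression through the origin on the linear scale (a blank
#' dilution must give ratio 0): `slope = sum(d * R) / sum(d^2)`. An
#' intercept fit and a log-log fit (geometric-mean slope, better behaved over
#' a 10^4 dynamic range) are available behind `method`. The uncentered
#' r-squared is reported and a warning raised below 0.9 (series
#' nonlinearity).
#'
#' @param series data.frame of calibration libraries with columns `dilution`,
#'   `n_sample`, `n_spike` (rows with `NA` dilution are ignored).
#' @param method `"origin"` (default), `"intercept"` or `"loglog"`.
#' @return a `calibration_fit` list: `slope`, `intercept`, `r_squared`,
#'   `method`, `n_points`, `points`.
#' @export
fit_dilution_curve <- function(series, method = c("origin", "intercept",
                                                  "loglog")) {
  method <- match.arg(method)
  pts <- series[!is.na(series$dilution), , drop = FALSE]
  if (nrow(pts) < 2 || length(unique(pts$dilution)) < 2) {
    stop("calibration requires >= 2 points with distinct dilutions")
  }
  d <- pts$dilution
  R <- ratio(pts)
  intercept <- 0
  if (method == "origin") {
    slope <- sum(d * R) / sum(d^2)
    r2 <- 1 - sum((R - slope * d)^2) / sum(R^2)
  } else if (method == "intercept") {
    fit <- stats::lm(R ~ d)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  } else {
    if (any(R <= 0)) stop("log-log fit requires positive ratios")
    lr <- log(R / d)
    slope <- exp(mean(lr))
    r2 <- 1 - sum((lr - mean(lr))^2) / sum(log(R)^2)
  }
  if (slope <= 0) warning("non-positive calibration slope")
  if (is.finite(r2) && r2 < 0.9) {
    warning(sprintf("calibration r-squared %.3f < 0.9: series is nonlinear",
                    r2))
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 method = method, n_points = nrow(pts),
                 points = data.frame(dilution = d, ratio = R)),
            class = "calibration_fit")
}

#' Convert ratios to percent repair relative to wild type
#'
#' `percent = 100 * (ratio / slope) / input_scale`: the calibration slope is
#' the ratio an undiluted wild-type library produces, and `input_scale`
#' corrects for loading more starting material (e.g. 2000x for repair-deficient
#' lines, whose measured ratio is inflated by the same factor).
#'
#' @param counts data.frame of libraries (see [library_counts()]).
#' @param fit a [fit_dilution_curve()] result.
#' @return data.frame with `sample_id`, `n_sample`, `n_spike`, `ratio`,
#'   `percent_of_wt`.
#' @export
percent_of_wt <- function(counts, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  scale <- if (is.null(counts$input_scale)) 1 else counts$input_scale
  if (any(is.na(scale))) stop("missing input_scale for ",
                              paste(counts$sample_id[is.na(scale)],
                                    collapse = ", "))
  R <- ratio(counts)
  data.frame(sample_id = counts$sample_id, n_sample = counts$n_sample,
             n_spike = counts$n_spike, ratio = R,
             percent_of_wt = 100 * (R / fit$slope) / scale)
}

#' Fold change of repair over a background condition
#'
#' E.g. the UV-irradiated mutant's percent-of-WT over the unirradiated
#' mutant's.
#'
#' @param percent_signal percent-of-WT of the signal condition.
#' @param percent_background percent-of-WT of the background (no-UV) condition.
#' @return numeric fold change.
#' @export
fold_over_background <- function(percent_signal, percent_background) {
  if (any(percent_background <= 0)) stop("background percent must be > 0")
  percent_signal / percent_background
}

#' Simulate a counts-level spike-in experiment
#'
#' Generates Poisson-distributed read counts for a wild-type dilution series
#' (constant expected spike-in depth, sample counts proportional to
#' `true_slope * dilution`) plus one mutant library with true relative repair
#' `mutant_relative`. Used to validate slope and percent-of-WT recovery
#' without simulating reads.
#'
#' @param seed random seed.
#' @param true_slope true undiluted sample:spike ratio.
#' @param spike_mean expected spike-in read count per library.
#' @param dilutions wild-type series dilution fractions.
#' @param mutant_relative true repair of the mutant relative to wild type.
#' @return data.frame of [library_counts()] rows; `attr(, "truth")` records
#'   the generating parameters.
#' @export
simulate_count_series <- function(seed = 1L, true_slope = 500,
                                  spike_mean = 5000,
                                  dilutions = c(1, 0.1, 0.01, 0.001, 1e-4),
                                  mutant_relative = 0.01) {
  set.seed(seed)
  rows <- lapply(seq_along(dilutions), function(i) {
    library_counts(sprintf("WT_dil%g", dilutions[i]),
                   stats::rpois(1, true_slope * dilutions[i] * spike_mean),
                   stats::rpois(1, spike_mean), dilution = dilutions[i])
  })
  mut <- library_counts("mutant",
                        stats::rpois(1, true_slope * mutant_relative *
                                       spike_mean),
                        stats::rpois(1, spike_mean))
  out <- do.call(rbind, c(rows, list(mut)))
  attr(out, "truth") <- list(true_slope = true_slope,
                             mutant_relative = mutant_relative)
  out
}

#' Quantify an experiment from a counts table
#'
#' Fits the calibration on the rows that carry a dilution and converts every
#' row to percent-of-WT.
#'
#' @param counts data.frame of [library_counts()] rows.
#' @param method calibration method (see [fit_dilution_curve()]).
#' @return list with `fit` and `quant` (the [percent_of_wt()] table).
#' @export
quantify_experiment <- function(counts, method = "origin") {
  fit <- fit_dilution_curve(counts, method)
  list(fit = fit, quant = percent_of_wt(counts, fit))
}
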