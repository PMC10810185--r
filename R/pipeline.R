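#' Species analysis presets
#'
#' Per-species parameters of the analysis: the read-length window with the
#' best dipyrimidine enrichment and the gene-selection thresholds
#' (human 24-30 nt, 5 kb / 5 kb; worm 20-28 nt, 1 kb / 500 bp; fly 25-30 nt,
#' 1 kb / 100 bp).
#'
#' @param species `"human"`, `"worm"` or `"fly"`.
#' @return list with `length_range`, `min_length`, `min_distance`.
#' @export
species_preset <- function(species = c("human", "worm", "fly")) {
  species <- match.arg(species)
  sel <- gene_selection_params(species)
  list(length_range = species_length_range(species),
       min_length = sel$min_length, min_distance = sel$min_distance)
}

.cfg_get <- function(config, field, default = NULL) {
  if (!is.null(config[[field]])) return(config[[field]])
  if (is.null(default)) stop("config field '", field, "' is missing")
  default
}

#' Default demo pipeline configuration
#'
#' A small, fully simulated worm-with-fly-spike-in experiment that exercises
#' every pipeline stage in a few minutes on one CPU.
#'
#' @param seed integer seed.
#' @param outdir output directory.
#' @return config list accepted by [run_all()].
#' @export
default_config <- function(seed = 1L, outdir = tempfile("xrquant_demo_")) {
  list(seed = as.integer(seed), outdir = outdir, simulate = TRUE,
       species = "worm", spike_species = "fly",
       simulation = list(
         genome_sizes = list(chr1 = 150000L, chrM = 12000L),
         n_genes = 25L, gene_length_range = c(1000L, 4000L),
         intergenic_gap = 400L, n_reads = 8000L,
         signal_fraction = 0.9, tcr_ratio = 4, mito_fraction = 0.05,
         duplicate_rate = 0.2, spike_reads = 1500L,
         dilutions = c(1, 0.1, 0.01)),
       spike_simulation = list(
         genome_sizes = list(spike1 = 40000L),
         n_reads = 4000L, mito_fraction = 0, signal_fraction = 0.95),
       window = c(4L, 10L), top_n = 5000L, k = 20L,
       mutant_relative = 0.01)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.as_sim_params <- function(lst, seed) {
  lst$genome_sizes <- unlist(lst$genome_sizes)
  if (!is.null(lst$length_weights)) {
    lst$length_weights <- unlist(lst$length_weights)
  }
  lst$seed <- seed
  do.call(simulation_params, lst)
}

# length weights restricted to a species window (uniform inside it)
.window_length_weights <- function(range) {
  lens <- seq(range[1], range[2])
  setNames(rep(1 / length(lens), length(lens)), lens)
}

.quantify_member <- function(member, sample_genome, spike_genome, config,
                             sample_range, spike_range) {
  trimmed <- trim_adaptor(member$raw, config$adaptor)
  uniq <- dedup(trimmed)
  parts <- partition_by_species(uniq, sample_genome, spike_genome,
                                config$species, config$spike_species)
  window <- .cfg_get(config, "window", c(4L, 10L))
  smp <- filter_damage(filter_length(parts$sample, sample_range), window)
  spk <- filter_damage(filter_length(parts$spike, spike_range), window)
  stages <- data.frame(
    sample_id = member$sample_id,
    stage = c("raw", "adaptor_trim", "dedup", "assigned_sample",
              "assigned_spike", "filtered_sample", "filtered_spike"),
    reads = c(nrow(member$raw), nrow(trimmed), nrow(uniq),
              nrow(parts$sample), nrow(parts$spike), nrow(smp), nrow(spk)))
  list(sample_reads = smp, spike_reads = spk, stages = stages,
       counts = library_counts(member$sample_id, nrow(smp), nrow(spk),
                               member$dilution))
}

#' Run the whole qXR-Seq pipeline from one configuration
#'
#' Simulation (or ingestion) -> adaptor trimming, deduplication,
#' species-partitioned exact alignment -> length and damage-signature
#' filtering -> composition profiles -> strand-resolved unit-gene metagene ->
#' dilution-curve calibration and percent-of-WT quantification. All outputs
#' are written under `config$outdir` and checksummed; the run is byte-identical
#' given the same seed. The first failing stage aborts the run with its name.
#'
#' @param config a config list (see [default_config()]) or the path to a YAML
#'   file holding one.
#' @param outdir optional override of `config$outdir`.
#' @return a report list: `stage_counts` (per-library per-stage read counts),
#'   `files` (paths and md5 checksums of every output), `fit` (calibration),
#'   `quant` (percent-of-WT table), `profile` (metagene), `range` (length
#'   window used).
#' @export
run_all <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(outdir)) config$outdir <- outdir
  outdir <- .cfg_get(config, "outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfg_get(config, "seed"))
  preset <- species_preset(.cfg_get(config, "species", "worm"))
  spike_preset <- species_preset(.cfg_get(config, "spike_species", "fly"))
  window <- .cfg_get(config, "window", c(4L, 10L))
  k <- .cfg_get(config, "k", 20L)
  files <- character(0)

  if (isTRUE(.cfg_get(config, "simulate", TRUE))) {
    sim <- .cfg_get(config, "simulation")
    sim$length_weights <- .window_length_weights(preset$length_range)
    params <- .stage("simulate", .as_sim_params(sim, seed))
    config$adaptor <- params$adaptor
    genome <- .stage("simulate", make_genome(params))
    genes <- .stage("simulate", make_genes(genome, params))
    base <- .stage("simulate",
                   simulate_library(genome, genes, params, sample_id = "WT",
                                    species = .cfg_get(config, "species",
                                                       "worm")))
    spike_sim <- .cfg_get(config, "spike_simulation")
    spike_sim$length_weights <- .window_length_weights(spike_preset$length_range)
    spike_sim$adaptor <- params$adaptor
    spike_sim$dilutions <- params$dilutions
    spike_params <- .stage("simulate", .as_sim_params(spike_sim, seed + 50L))
    spike_genome <- .stage("simulate", make_genome(spike_params))
    spike <- .stage("simulate",
                    simulate_library(spike_genome, NULL, spike_params,
                                     sample_id = "spike",
                                     species = .cfg_get(config,
                                                        "spike_species",
                                                        "fly"),
                                     id_prefix = "sp"))
    series <- .stage("simulate",
                     make_spikein_series(base, spike, params$dilutions,
                                         params$spike_reads,
                                         seed = seed + 100L))
    mut_rel <- .cfg_get(config, "mutant_relative", 0.01)
    mut_params <- params
    mut_params$seed <- seed + 60L
    mut_base <- .stage("simulate",
                       simulate_library(genome, genes, mut_params,
                                        sample_id = "mutant",
                                        species = base$species,
                                        id_prefix = "m",
                                        seed = seed + 62L))
    mutant <- .stage("simulate",
                     make_spikein_series(mut_base, spike, mut_rel,
                                         params$spike_reads,
                                         seed = seed + 200L))[[1]]
    mutant$sample_id <- "mutant"
    mutant$counts_dilution <- NA_real_
    mutant$dilution <- NA_real_

    files["genome_sample"] <- file.path(outdir, "genome_sample.fa")
    write_fasta(genome, files["genome_sample"])
    files["genome_spike"] <- file.path(outdir, "genome_spike.fa")
    write_fasta(spike_genome, files["genome_spike"])
    files["genes"] <- file.path(outdir, "genes.bed")
    write_bed6_genes(genes, files["genes"])
    files["manifest"] <- file.path(outdir, "manifest_wt.tsv")
    write.table(base$manifest, files["manifest"], sep = "\t", quote = FALSE,
                row.names = FALSE)

    members <- c(series, list(mutant))
    quant_in <- .stage("quantify", {
      lapply(members, .quantify_member, sample_genome = genome,
             spike_genome = spike_genome, config = config,
             sample_range = preset$length_range,
             spike_range = spike_preset$length_range)
    })
    stage_counts <- do.call(rbind, lapply(quant_in, `[[`, "stages"))
    counts <- do.call(rbind, lapply(quant_in, `[[`, "counts"))
    fit <- .stage("quantify", fit_dilution_curve(counts))
    quant <- .stage("quantify", percent_of_wt(counts, fit))

    undiluted <- quant_in[[which.max(counts$dilution)]]
    comp_reads <- .stage("composition",
                         trim_5prime_to(
                           filter_length(undiluted$sample_reads,
                                         c(max(preset$length_range[1], k),
                                           preset$length_range[2])), k))
    profile_comp <- .stage("composition", dinucleotide_profile(comp_reads))
    meta <- .stage("metagene",
                   metagene_profile(undiluted$sample_reads, genes,
                                    preset$min_length, preset$min_distance,
                                    contig_lengths = nchar(genome),
                                    top_n = .cfg_get(config, "top_n", 5000L),
                                    total_mapped_reads =
                                      nrow(undiluted$sample_reads)))

    files["reads_wt"] <- file.path(outdir, "reads_wt_filtered.bed")
    write_bed6_reads(undiluted$sample_reads, files["reads_wt"])
  } else {
    genome <- .stage("ingest", read_fasta(.cfg_get(config, "genome")))
    genes <- .stage("ingest", read_bed6_genes(.cfg_get(config, "genes")))
    reads <- .stage("ingest",
                    read_bed6_reads(.cfg_get(config, "reads"),
                                    genome = genome))
    sized <- .stage("filter", filter_length(reads, preset$length_range))
    filtered <- .stage("filter", filter_damage(sized, window))
    stage_counts <- data.frame(sample_id = "sample",
                               stage = c("input", "length_filter",
                                         "damage_filter"),
                               reads = c(nrow(reads), nrow(sized),
                                         nrow(filtered)))
    comp_reads <- .stage("composition",
                         trim_5prime_to(
                           filter_length(filtered,
                                         c(max(preset$length_range[1], k),
                                           preset$length_range[2])), k))
    profile_comp <- .stage("composition", dinucleotide_profile(comp_reads))
    meta <- .stage("metagene",
                   metagene_profile(filtered, genes, preset$min_length,
                                    preset$min_distance,
                                    contig_lengths = nchar(genome),
                                    top_n = .cfg_get(config, "top_n", 5000L)))
    fit <- NULL
    quant <- NULL
    files["reads_filtered"] <- file.path(outdir, "reads_filtered.bed")
    write_bed6_reads(filtered, files["reads_filtered"])
  }

  files["profile"] <- file.path(outdir, "profile.tsv")
  write_profile_tsv(meta$profile, files["profile"])
  if (!is.null(profile_comp$nuclear)) {
    files["dinuc_nuclear"] <- file.path(outdir, "dinucleotide_nuclear.tsv")
    write_dinucleotide_tsv(profile_comp$nuclear, files["dinuc_nuclear"])
  }
  if (!is.null(profile_comp$mitochondrial)) {
    files["dinuc_mito"] <- file.path(outdir, "dinucleotide_mitochondrial.tsv")
    write_dinucleotide_tsv(profile_comp$mitochondrial, files["dinuc_mito"])
  }
  if (!is.null(quant)) {
    files["quant"] <- file.path(outdir, "quant.tsv")
    qt <- quant
    qt$ratio <- sprintf("%.12g", qt$ratio)
    qt$percent_of_wt <- sprintf("%.12g", qt$percent_of_wt)
    write.table(qt, files["quant"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    files["calibration"] <- file.path(outdir, "calibration.tsv")
    cal <- data.frame(dilution = fit$points$dilution,
                      ratio = sprintf("%.12g", fit$points$ratio),
                      slope = sprintf("%.12g", fit$slope),
                      r_squared = sprintf("%.12g", fit$r_squared))
    write.table(cal, files["calibration"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  files["stage_report"] <- file.path(outdir, "stage_report.tsv")
  write.table(stage_counts, files["stage_report"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  checksums <- tools::md5sum(unname(files))
  report <- list(stage_counts = stage_counts,
                 files = data.frame(name = names(files), path = unname(files),
                                    md5 = unname(checksums)),
                 fit = fit, quant = quant, profile = meta$profile,
                 range = preset$length_range)
  report
}
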