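test_that("generator is byte-deterministic under a fixed seed", {
  p <- simulation_params(seed = 11, n_reads = 500)
  expect_identical(make_genome(p), make_genome(p))
  g <- make_genome(p)
  expect_identical(make_genes(g, p), make_genes(g, p))
  genes <- make_genes(g, p)
  l1 <- simulate_library(g, genes, p)
  l2 <- simulate_library(g, genes, p)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$raw, l2$raw)
  expect_identical(l1$manifest, l2$manifest)
})

test_that("genome GC content matches the binomial expectation", {
  # z-scores across seeds: mean within 3 SE, no single draw beyond 4 SD
  z <- vapply(1:5, function(s) {
    p <- simulation_params(seed = s, genome_sizes = c(chr1 = 100000L,
                                                      chrM = 5000L))
    g <- make_genome(p)
    n <- nchar(g[["chr1"]])
    gc <- sum(strsplit(g[["chr1"]], "")[[1]] %in% c("G", "C"))
    (gc - 0.5 * n) / sqrt(n * 0.25)
  }, numeric(1))
  expect_lt(abs(mean(z)), 3 / sqrt(5))
  expect_lt(max(abs(z)), 4)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(simulation_params(genome_sizes = c(chr1 = 500L, chrM = 2000L)),
               "1 kb")
  expect_error(simulation_params(genome_sizes = c(chr1 = 5000L)), "chrM")
  expect_error(simulation_params(length_weights = c("19" = 0.5, "20" = 0.4)),
               "sum to 1")
  expect_error(simulation_params(tcr_ratio = 0.5), "tcr_ratio")
  expect_error(simulation_params(dilutions = c(1, 2)), "dilutions")
})

test_that("gene placement respects gaps and packs deterministically", {
  p <- simulation_params(seed = 2, n_genes = 10L, intergenic_gap = 300L)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  expect_equal(nrow(genes), 10L)
  ord <- order(genes$start)
  gaps <- genes$start[ord][-1] - genes$end[ord][-10]
  expect_true(all(gaps >= 300))
  expect_true(all(genes$end <= nchar(g[genes$contig])))
  # infeasible packing errors
  p2 <- simulation_params(seed = 2, n_genes = 100L,
                          genome_sizes = c(chr1 = 50000L, chrM = 5000L),
                          gene_length_range = c(2000L, 3000L))
  g2 <- make_genome(p2)
  expect_error(make_genes(g2, p2), "infeasible packing")
})

test_that("read coordinates always agree with their sequences", {
  p <- simulation_params(seed = 21, n_reads = 3000)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  lib <- simulate_library(g, genes, p)
  ref <- substring(g[lib$reads$contig], lib$reads$start + 1, lib$reads$end)
  neg <- lib$reads$strand == "-"
  ref[neg] <- revcomp(ref[neg])
  expect_equal(unname(ref), lib$reads$sequence)
})

test_that("forced offset places the dipyrimidine exactly", {
  p <- simulation_params(seed = 8, n_reads = 800, signal_fraction = 1,
                         mito_fraction = 0,
                         damage_offset_weights = c("5" = 1))
  g <- make_genome(p)
  genes <- make_genes(g, p)
  lib <- simulate_library(g, genes, p)
  L <- nchar(lib$reads$sequence)
  pair <- substring(lib$reads$sequence, L - 5, L - 4)
  expect_true(all(pair %in% c("CC", "CT", "TC", "TT")))
  expect_true(all(has_dipyrimidine_3prime(lib$reads$sequence)))
  expect_true(all(lib$manifest$damage_offset == 5))
})

test_that("tcr_ratio 1 balances TS and NTS within binomial error", {
  p <- simulation_params(seed = 13, n_reads = 6000, signal_fraction = 1,
                         mito_fraction = 0, tcr_ratio = 1)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  lib <- simulate_library(g, genes, p)
  ts <- sum(lib$manifest$strand_class == "TS", na.rm = TRUE)
  nts <- sum(lib$manifest$strand_class == "NTS", na.rm = TRUE)
  n <- ts + nts
  expect_lt(abs(ts - n / 2), 3 * sqrt(n * 0.25))
})

test_that("mitochondrial reads are always signature-free background", {
  p <- simulation_params(seed = 4, n_reads = 4000, mito_fraction = 0.3)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  lib <- simulate_library(g, genes, p)
  chrm <- lib$manifest$contig == "chrM"
  expect_gt(sum(chrm), 0)
  expect_false(any(lib$manifest$signal[chrm]))
  expect_equal(unique(lib$manifest$origin[chrm]), "chrM")
})

test_that("duplicate emission matches the manifest's distinct sequences", {
  p <- simulation_params(seed = 6, n_reads = 1000, duplicate_rate = 0.5)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  lib <- simulate_library(g, genes, p)
  expect_gt(nrow(lib$raw), 1000)
  uniq <- dedup(trim_adaptor(lib$raw, p$adaptor))
  expect_equal(nrow(uniq), length(unique(lib$manifest$sequence)))
})

test_that("spike-in series thins the base library and keeps the spike fixed", {
  p <- simulation_params(seed = 30, n_reads = 10000, mito_fraction = 0)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  base <- simulate_library(g, genes, p)
  sp_params <- simulation_params(seed = 31, n_reads = 3000,
                                 genome_sizes = c(spk1 = 30000L),
                                 mito_fraction = 0)
  sg <- make_genome(sp_params)
  spike <- simulate_library(sg, NULL, sp_params, sample_id = "spike",
                            species = "spike", id_prefix = "sp")
  series <- make_spikein_series(base, spike, dilutions = c(1, 0.1),
                                spike_reads = 2000L, seed = 77)
  n_spike <- vapply(series, function(m) sum(m$reads$species == "spike"),
                    integer(1))
  expect_equal(n_spike, c(2000L, 2000L))
  expect_equal(sum(series[[1]]$reads$species == "sample"), 10000L)
  kept <- sum(series[[2]]$reads$species == "sample")
  expect_lt(abs(kept - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_equal(series[[2]]$dilution, 0.1)
  # raw reads subset consistently with the retained molecules
  ids <- series[[2]]$reads$read_id
  expect_setequal(unique(sub("_dup$", "", series[[2]]$raw$read_id)), ids)
  expect_error(make_spikein_series(base, spike, 1, 5000L), "spike library")
  expect_error(make_spikein_series(base, spike, c(0.5, 2), 100L), "dilutions")
})
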