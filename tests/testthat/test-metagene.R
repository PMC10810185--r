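mk_genes <- function(start, end, strand = "+", contig = "chr1") {
  data.frame(gene_id = sprintf("g%02d", seq_along(start)), contig = contig,
             start = start, end = end, strand = strand)
}

test_that("gene selection applies length and distance thresholds", {
  close_pair <- mk_genes(c(1000, 2600), c(2200, 4000))  # 400 bp apart
  expect_equal(nrow(select_genes(close_pair, 1000, 500)), 0L)
  expect_equal(nrow(select_genes(close_pair, 1000, 400)), 2L)

  lone <- mk_genes(20000, 26000)
  expect_equal(select_genes(lone, 5000, 5000)$gene_id, "g01")
  expect_equal(nrow(select_genes(mk_genes(20000, 24000), 5000, 5000)), 0L)

  flagged <- select_genes(lone, 5000, 5000,
                          contig_lengths = c(chr1 = 27000))
  expect_true(flagged$flank_truncated)  # downstream flank clipped
})

test_that("gene selection matches the O(n^2) oracle on a random fixture", {
  set.seed(60)
  for (rep in 1:3) {
    start <- sort(sample(0:200000, 50))
    len <- sample(500:8000, 50, replace = TRUE)
    genes <- mk_genes(start, start + len,
                      strand = sample(c("+", "-"), 50, replace = TRUE),
                      contig = sample(c("chr1", "chr2"), 50, replace = TRUE))
    for (md in c(100, 500, 5000)) {
      got <- select_genes(genes, 1000, md)$gene_id
      expect_equal(got, oracle_select_genes(genes, 1000, md))
    }
  }
})

test_that("unit-gene binning follows the 150-bin scheme", {
  g <- mk_genes(10000, 11000)[1, ]
  b <- bin_gene(g)
  expect_equal(nrow(b), 150L)
  expect_true(all(b$width[b$region == "body"] == 10))
  expect_equal(c(b$start[26], b$end[26]), c(10000L, 10010L))
  expect_equal(c(b$start[1], b$end[1]), c(8000L, 8080L))
  expect_equal(c(b$start[126], b$end[126]), c(11000L, 11080L))

  gm <- mk_genes(10000, 11000, strand = "-")[1, ]
  bm <- bin_gene(gm)
  expect_equal(c(bm$start[26], bm$end[26]), c(10990L, 11000L))
  expect_equal(c(bm$start[1], bm$end[1]), c(12920L, 13000L))
  expect_equal(c(bm$start[150], bm$end[150]), c(8000L, 8080L))

  g3 <- mk_genes(10000, 11003)[1, ]
  b3 <- bin_gene(g3)
  body_w <- b3$width[b3$region == "body"]
  expect_equal(sum(body_w == 10), 97L)
  expect_equal(sum(body_w == 11), 3L)
  expect_equal(sum(body_w), 1003L)
  expect_true(all(body_w[98:100] == 11))  # remainder on the last body bins

  expect_error(bin_gene(mk_genes(10, 80)[1, ]), "shorter than 100")

  # flank clipping at contig edges
  edge <- bin_gene(mk_genes(500, 2000)[1, ], contig_length = 2500)
  expect_true(all(edge$start >= 0))
  expect_true(all(edge$end <= 2500))
  expect_true(any(edge$width == 0))
})

test_that("body bins partition random gene lengths exactly", {
  set.seed(61)
  for (L in sample(100:30000, 200)) {
    b <- bin_gene(mk_genes(5000, 5000 + L)[1, ])
    w <- b$width[b$region == "body"]
    expect_equal(sum(w), L)
    expect_lte(diff(range(w)), 1)
  }
})

test_that("reads count toward TS/NTS per the antisense convention", {
  genes <- mk_genes(10000, 11000)
  bins <- bin_genes(genes)
  # read fully inside the first upstream flank bin, same strand as gene -> NTS
  r_plus <- aligned_reads("a", "chr1", 8010, 8030, "+", rand_dna(20, 1))
  c1 <- assign_reads(r_plus, bins)
  expect_equal(c1$nts["g01", 1], 1L)
  expect_equal(sum(c1$ts), 0L)
  # opposite strand -> TS
  r_minus <- r_plus; r_minus$strand <- "-"
  c2 <- assign_reads(r_minus, bins)
  expect_equal(c2$ts["g01", 1], 1L)
  # overlap threshold: a 9/11 split counts only in the 11-bp side;
  # an exact 10/10 split reaches 50% in both bins
  r_split <- aligned_reads("s", "chr1", 10009, 10029, "+", rand_dna(20, 2))
  c3 <- assign_reads(r_split, bins)
  expect_equal(sum(c3$nts), 1L)
  expect_equal(c3$nts["g01", 27], 1L)
  r_even <- aligned_reads("e", "chr1", 10010, 10030, "+", rand_dna(20, 3))
  c4 <- assign_reads(r_even, bins)
  expect_equal(sum(c4$nts), 2L)
  # bound: total counted pairs <= reads * floor(1/f)
  expect_lte(sum(c4$ts) + sum(c4$nts), 1 * floor(1 / 0.5))
})

test_that("gene ranking uses the pseudocounted TS/NTS ratio with tie-breaks", {
  counts <- list(ts = matrix(c(9, 3, 1, 0), 4, 150 / 150 * 1), nts = NULL)
  # build a proper counts object: 4 genes, single-column matrices padded
  ts <- matrix(0L, 4, 150, dimnames = list(paste0("g", 1:4), 1:150))
  nts <- ts
  ts[, 1] <- c(90, 30, 10, 0)
  nts[, 1] <- c(10, 10, 10, 0)
  counts <- list(ts = ts, nts = nts, gene_ids = paste0("g", 1:4))
  expect_equal(rank_genes_ts_nts(counts, 2), c("g1", "g2"))
  # all-zero: ratio 1 everywhere, deterministic id tie-break
  zero <- list(ts = ts * 0L, nts = nts * 0L, gene_ids = paste0("g", 4:1))
  expect_equal(rank_genes_ts_nts(zero, 4), paste0("g", 1:4))
})

test_that("ranking enriches for genuinely TCR-biased genes", {
  set.seed(62)
  ng <- 40
  ts <- matrix(0L, ng, 150, dimnames = list(sprintf("g%02d", 1:ng), 1:150))
  nts <- ts
  # first 20 genes have 4:1 odds, last 20 have 1:1, ~100 reads each
  for (i in 1:ng) {
    n <- rpois(1, 100)
    p <- if (i <= 20) 0.8 else 0.5
    k <- rbinom(1, n, p)
    ts[i, 1] <- k
    nts[i, 1] <- n - k
  }
  top <- rank_genes_ts_nts(list(ts = ts, nts = nts,
                                gene_ids = rownames(ts)), 20)
  hits <- sum(top %in% sprintf("g%02d", 1:20))
  pval <- phyper(hits - 1, 20, 20, 20, lower.tail = FALSE)
  expect_lt(pval, 1e-6)
})

test_that("RPKM arithmetic and scale invariance", {
  ts <- matrix(0L, 1, 150, dimnames = list("g1", 1:150))
  nts <- ts
  ts[1, 1] <- 5L
  w <- matrix(80L, 1, 150, dimnames = list("g1", 1:150))
  counts <- list(ts = ts, nts = nts, width = w, gene_ids = "g1")
  prof <- profile_rpkm(counts, 1e6)
  expect_equal(prof$TS[1], 62.5)
  # doubling every count and the total leaves values unchanged
  counts2 <- list(ts = ts * 2L, nts = nts * 2L, width = w, gene_ids = "g1")
  expect_equal(profile_rpkm(counts2, 2e6)$TS, prof$TS)
  expect_error(profile_rpkm(counts, 0), "total_mapped_reads")
})

test_that("flipping every gene strand exchanges and reverses TS/NTS", {
  p <- simulation_params(seed = 63, n_reads = 4000, signal_fraction = 1,
                         mito_fraction = 0)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  # exact symmetry requires identical bin partitions on both strandings
  genes$end <- genes$start + ((genes$end - genes$start) %/% 100L) * 100L
  lib <- simulate_library(g, genes, p)
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  c1 <- assign_reads(lib$reads, bin_genes(genes, nchar(g)))
  c2 <- assign_reads(lib$reads, bin_genes(flipped, nchar(g)))
  expect_equal(c2$ts, c1$nts[, 150:1, drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(c2$nts, c1$ts[, 150:1, drop = FALSE],
               ignore_attr = TRUE)
})
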