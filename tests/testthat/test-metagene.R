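test_that("flank bins span exactly 100 kb each side at genome-scale defaults", {
  g <- toy_genes()[1L, ]
  bins <- build_gene_bins(g)
  up <- bins[bins$region == "UTSS", ]
  dn <- bins[bins$region == "DTTS", ]
  # widths before clipping: reconstructed from the unclipped downstream side
  expect_equal(sum(dn$end - dn$start), 100000)
  expect_equal(nrow(up), 20L)
  expect_true(all((up$end - up$start)[!up$clipped] == 5000))
  # this gene starts at 1,000 so most of its upstream flank is clipped at 0
  expect_true(any(up$clipped))
  expect_equal(min(up$start), 0)
})

test_that("body bins partition the gene exactly under the floor rule", {
  # length 20 -> twenty 1 bp bins
  g <- list(gene_id = "g", chrom = "c", strand = "+", start = 100L, end = 120L)
  gb <- build_gene_bins(as.data.frame(g))
  gb <- gb[gb$region == "GB", ]
  expect_equal(gb$end - gb$start, rep(1, 20))
  expect_equal(gb$start, 100 + 0:19)
  # length 50 -> floor-rule widths, alternating 2 and 3
  g$end <- 150L
  gb <- build_gene_bins(as.data.frame(g))
  gb <- gb[gb$region == "GB", ]
  expect_equal(gb$end - gb$start, rep(c(2, 3), 10))
  # partition property on assorted lengths and both strands (interval oracle)
  for (L in c(20L, 21L, 37L, 50L, 137L, 9999L)) for (s in c("+", "-")) {
    g2 <- data.frame(gene_id = "g", chrom = "c", strand = s,
                     start = 1000L, end = 1000L + L)
    gb <- build_gene_bins(g2)
    gb <- gb[gb$region == "GB", ]
    gb <- gb[order(gb$start), ]
    expect_equal(gb$start[1L], 1000)
    expect_equal(gb$end[20L], 1000 + L)
    expect_true(all(gb$start[-1L] == gb$end[-20L]))  # no gaps, no overlaps
    expect_true(all(gb$end > gb$start))
  }
  # genes shorter than the bin count are skipped with a message
  short <- data.frame(gene_id = "tiny", chrom = "c", strand = "+",
                      start = 0L, end = 10L)
  expect_message(expect_null(build_gene_bins(short)), "skipped")
})

test_that("bins are oriented 5' to 3' of the gene on both strands", {
  gplus <- data.frame(gene_id = "p", chrom = "c", strand = "+",
                      start = 300000L, end = 301000L)
  gminus <- data.frame(gene_id = "m", chrom = "c", strand = "-",
                       start = 300000L, end = 301000L)
  bp <- build_gene_bins(gplus)
  bm <- build_gene_bins(gminus)
  # upstream bin 0 is farthest from the TSS: left of start for +, right of end for -
  expect_equal(bp$start[bp$region == "UTSS" & bp$bin == 0], 300000 - 100000)
  expect_equal(bm$end[bm$region == "UTSS" & bm$bin == 0], 301000 + 100000)
  # body bin 0 hugs the TSS on each strand
  expect_equal(bp$start[bp$region == "GB" & bp$bin == 0], 300000)
  expect_equal(bm$end[bm$region == "GB" & bm$bin == 0], 301000)
  # downstream bin 0 hugs the TTS
  expect_equal(bp$start[bp$region == "DTTS" & bp$bin == 0], 301000)
  expect_equal(bm$end[bm$region == "DTTS" & bm$bin == 0], 300000)
  # right-edge clipping against a contig length is flagged
  bclip <- build_gene_bins(gplus, chrom_length = 320000L)
  expect_true(any(bclip$clipped[bclip$region == "DTTS"]))
  expect_lte(max(bclip$end), 320000)
})

test_that("weighted level pools reads, distinguishing it from a site average", {
  ct <- make_ct(pos = c(1L, 5L), protected = c(1L, 1L), total = c(2L, 18L))
  wl <- weighted_level(ct, "chr1", 0, 10)
  expect_equal(wl$level, 0.10)       # 2/20, not mean(1/2, 1/18) = 0.2778
  expect_equal(wl$total, 20)
  # all protected -> 1; empty interval -> missing, never 0
  expect_equal(weighted_level(make_ct(3L, 7L, 7L), "chr1", 0, 10)$level, 1)
  expect_true(is.na(weighted_level(ct, "chr1", 100, 200)$level))
  # non-CG calls inside the interval are ignored
  mix <- call_table(data.frame(chrom = "chr1", pos = c(1L, 2L), strand = "+",
                               context = c("CG", "CHH"),
                               protected = c(1L, 5L), total = c(4L, 5L)))
  expect_equal(weighted_level(mix, "chr1", 0, 10)$level, 0.25)
})

test_that("quintile metagene pooling equals a brute-force per-read oracle", {
  genes <- gene_models(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1", strand = c("+", "-", "+"),
    start = c(1000L, 3000L, 5000L), end = c(1100L, 3100L, 5100L),
    exonic_length = c(80L, 80L, 80L)))
  # 5 scored genes incl. two off-annotation so each quintile is one gene
  asn <- assign_quintiles(setNames(c(1, 2, 3, 4, 5),
                                   c("gA", "x1", "gB", "x2", "gC")))
  set.seed(21)
  pos <- sort(sample(0:6000, 400))
  ct <- make_ct(pos = pos, protected = rbinom(400, 3, 0.3), total = 3L)
  # quintiles 2 and 4 hold only off-annotation genes: empty-profile warnings
  prof <- suppressWarnings(
    compute_metagene(ct, genes, asn, n_flank_bins = 4L,
                     flank_bin_size = 25L, n_body_bins = 5L))
  # oracle: per gene/bin interval, sum reads by brute force over all calls
  for (q in c(1L, 3L, 5L)) {
    gid <- c("gA", "gB", "gC")[match(q, c(1L, 3L, 5L))]
    bins <- build_gene_bins(genes[genes$gene_id == gid, ], n_flank_bins = 4L,
                            flank_bin_size = 25L, n_body_bins = 5L)
    for (r in c("UTSS", "GB", "DTTS")) for (b in 0:(if (r == "GB") 4L else 3L)) {
      iv <- bins[bins$region == r & bins$bin == b, ]
      expected <- weighted_level(ct, iv$chrom, iv$start, iv$end)
      got <- prof[prof$quintile == q & prof$region == r & prof$bin == b, ]
      expect_equal(got$protected, expected$protected)
      expect_equal(got$total, expected$total)
      expect_equal(got$level, expected$level)
    }
  }
  # single gene, single covered bin: that bin matches, the rest are missing
  lone <- make_ct(pos = 1005L, protected = 2L, total = 4L)
  p1 <- suppressWarnings(withCallingHandlers(
    compute_metagene(lone, genes, asn, n_flank_bins = 4L,
                     flank_bin_size = 25L, n_body_bins = 5L),
    warning = function(w) expect_match(conditionMessage(w), "no covered bins")))
  hit <- p1[!is.na(p1$level), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$quintile, 1L)
  expect_equal(hit$region, "GB")
  expect_equal(hit$level, 0.5)
  expect_equal(hit$n_genes, 1L)
})

test_that("a uniform methylome yields a flat profile and enrichment shows where configured", {
  # same per-read protected-call probability everywhere -> no TSS structure
  cfg <- small_cfg(seed = 31, coverage = 6,
                   gb_hmc_prob = rep(0.02, 5), background_hmc_prob = 0.02)
  sim <- simulate_dataset(cfg)
  asn <- assign_quintiles(normalize_expression(sim$expression, sim$genes))
  prof <- compute_metagene(sim$calls, sim$genes, asn,
                           flank_bin_size = cfg$flank_bin_size,
                           chrom_lengths = cfg$chrom_lengths)
  glob <- global_5hmCG(sim$calls)$pct_5hmCG / 100
  ok <- !is.na(prof$level) & prof$total >= 50
  sd3 <- 3 * sqrt(glob * (1 - glob) / prof$total[ok])
  expect_gt(mean(abs(prof$level[ok] - glob) <= sd3), 0.98)
  # gene-body enrichment only in quintile 5 appears only there
  cfg2 <- small_cfg(seed = 32, coverage = 6,
                    gb_hmc_prob = c(0.02, 0.02, 0.02, 0.02, 0.2),
                    background_hmc_prob = 0.02)
  sim2 <- simulate_dataset(cfg2)
  asn2 <- assign_quintiles(normalize_expression(sim2$expression, sim2$genes))
  prof2 <- compute_metagene(sim2$calls, sim2$genes, asn2,
                            flank_bin_size = cfg2$flank_bin_size,
                            chrom_lengths = cfg2$chrom_lengths)
  pool <- function(q, r) {
    rows <- prof2$quintile == q & prof2$region == r & !is.na(prof2$total)
    sum(prof2$protected[rows]) / sum(prof2$total[rows])
  }
  expect_gt(pool(5, "GB"), 2 * max(pool(5, "UTSS"), pool(5, "DTTS")))
  expect_lt(abs(pool(1, "GB") - pool(1, "UTSS")), 0.01)
})

test_that("profiles are invariant under reverse-complementing the toy genome", {
  cfg <- small_cfg(seed = 33, coverage = 4)
  sim <- simulate_dataset(cfg)
  asn <- assign_quintiles(normalize_expression(sim$expression, sim$genes))
  args <- list(flank_bin_size = cfg$flank_bin_size,
               chrom_lengths = cfg$chrom_lengths)
  prof <- do.call(compute_metagene, c(list(sim$calls, sim$genes, asn), args))
  # mirror every coordinate and flip strands
  len <- cfg$chrom_lengths
  calls <- as.data.frame(sim$calls)
  calls$pos <- as.integer(len[calls$chrom]) - 1L - calls$pos
  calls$strand <- ifelse(calls$strand == "+", "-", "+")
  flipped_calls <- call_table(calls, sample_id = sample_id(sim$calls))
  genes <- as.data.frame(sim$genes)
  s <- genes$start
  genes$start <- as.integer(len[genes$chrom]) - genes$end
  genes$end <- as.integer(len[genes$chrom]) - s
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  prof_f <- do.call(compute_metagene,
                    c(list(flipped_calls, gene_models(genes), asn), args))
  expect_equal(prof_f$protected, prof$protected)
  expect_equal(prof_f$total, prof$total)
  expect_equal(prof_f$level, prof$level)
})

test_that("binomial subsampling thins coverage as advertised", {
  cfg <- small_cfg(seed = 41, coverage = 5)
  sim <- simulate_dataset(cfg)
  # identity at fraction 1
  expect_identical(subsample_calls(sim$calls, 1, seed = 1), sim$calls)
  expect_error(subsample_calls(sim$calls, 1.5, seed = 1),
               class = "hydroxymeta_validation_error")
  expect_error(subsample_calls(sim$calls, 0.5),
               class = "hydroxymeta_validation_error")  # seed required
  n_reads <- sum(as.numeric(sim$calls$total))
  expect_gt(n_reads, 100000)
  thin <- subsample_calls(sim$calls, 0.5, seed = 99)
  expect_lt(abs(sum(as.numeric(thin$total)) - 0.5 * n_reads),
            3 * sqrt(n_reads * 0.25))
  expect_true(all(thin$total >= 1))
  expect_true(all(thin$protected <= thin$total))
  # deterministic given the seed; coverage scales with the fraction
  expect_identical(as.data.frame(subsample_calls(sim$calls, 0.5, seed = 99)),
                   as.data.frame(thin))
  cov_full <- estimate_coverage(sim$calls, sim$truth$n_reference_cytosines)
  cov_thin <- estimate_coverage(thin, sim$truth$n_reference_cytosines)
  expect_equal(cov_thin / cov_full, 0.5, tolerance = 0.02)
})

test_that("profiles are stable under subsampling and a plot can be drawn", {
  cfg <- small_cfg(seed = 43, coverage = 10)
  sim <- simulate_dataset(cfg)
  asn <- assign_quintiles(normalize_expression(sim$expression, sim$genes))
  args <- list(flank_bin_size = cfg$flank_bin_size,
               chrom_lengths = cfg$chrom_lengths)
  full <- do.call(compute_metagene, c(list(sim$calls, sim$genes, asn), args))
  for (f in c(0.5, 0.1)) {
    thin <- subsample_calls(sim$calls, f, seed = 7)
    prof <- do.call(compute_metagene, c(list(thin, sim$genes, asn), args))
    ok <- !is.na(prof$level) & !is.na(full$level) & prof$total > 0
    sd3 <- 3 * sqrt(pmax(full$level[ok] * (1 - full$level[ok]), 1e-6) / prof$total[ok])
    expect_gt(mean(abs(prof$level[ok] - full$level[ok]) <= sd3), 0.97)
  }
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(full))
})
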