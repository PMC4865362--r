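#' Configuration for the synthetic TAB-seq data generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a toy
#' two-chromosome genome, 200 genes with log-normally distributed lengths,
#' a 16-sample expression matrix (mirroring averaging over 16 adipose tissue
#' RNA-seq samples), per-quintile gene-body 5hmCG signal with a 3.8-fold
#' spread between the highest and lowest quintile, fully-5mC lambda and
#' fully-5hmC pUC19 spike-ins, and Poisson read depth in genome equivalents.
#'
#' The per-quintile `gb_hmc_prob` and the `background_hmc_prob` are apparent
#' per-read protected-call probabilities at genomic CG sites — the chance a
#' read reports C, with assay noise folded in. Spike-ins follow the assay
#' chemistry exactly: lambda CG sites read C at `nonconv_5mC`, pUC19 CG
#' sites at `protection_rate`, and all non-CG cytosines at `nonconv_C`.
#'
#' @param seed mandatory RNG seed.
#' @param chrom_lengths named integer vector of contig lengths
#'   (default two 500 kb chromosomes).
#' @param gc_content base composition of the toy genome.
#' @param n_genes number of genes (default 200).
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_min,gene_length_max
#'   log-normal gene-length distribution (bp), clamped to
#'   `[gene_length_min, gene_length_max]`.
#' @param exonic_fraction range of the exonic fraction of each gene span.
#' @param n_expr_samples number of expression pseudo-samples (default 16).
#' @param expr_noise_sdlog log-normal sd of per-sample expression noise.
#' @param gb_hmc_prob per-read protected-call probability at gene-body CG
#'   sites, one value per quintile 1..5 (defaults 0.010 .. 0.038, a 3.8-fold
#'   quintile-5 : quintile-1 ratio).
#' @param background_hmc_prob protected-call probability at CG sites outside
#'   gene bodies (flanks and intergenic).
#' @param nonconv_5mC 5mC non-conversion rate (lambda truth, default 0.03).
#' @param nonconv_C unmodified-cytosine non-conversion rate (default 0.005).
#' @param protection_rate beta-GT protection rate (pUC19 truth,
#'   default 0.52).
#' @param coverage genomic read depth in genome equivalents (0.2-13 is the
#'   regime of interest; default 1).
#' @param spikein_coverage read depth on the spike-in sequences.
#' @param lambda_length,puc19_length spike-in sequence lengths (bp); pUC19
#'   defaults to its real 2,686 bp plasmid length.
#' @param flank_bin_size flank bin width (bp) to use in metagene analyses of
#'   this toy genome; scaled down from the genome-scale 5 kb default so 20
#'   bins fit the toy chromosomes.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                       gc_content = 0.42,
                       n_genes = 200L,
                       gene_length_meanlog = log(3000),
                       gene_length_sdlog = 0.5,
                       gene_length_min = 500L,
                       gene_length_max = 12000L,
                       exonic_fraction = c(0.3, 0.9),
                       n_expr_samples = 16L,
                       expr_noise_sdlog = 0.5,
                       gb_hmc_prob = c(0.010, 0.017, 0.024, 0.031, 0.038),
                       background_hmc_prob = 0.020,
                       nonconv_5mC = 0.03,
                       nonconv_C = 0.005,
                       protection_rate = 0.52,
                       coverage = 1,
                       spikein_coverage = 30,
                       lambda_length = 5000L,
                       puc19_length = 2686L,
                       flank_bin_size = 100L) {
  if (missing(seed)) stop_validation("'seed' is required")
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              gc_content = gc_content, n_genes = as.integer(n_genes),
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              gene_length_min = as.integer(gene_length_min),
              gene_length_max = as.integer(gene_length_max),
              exonic_fraction = exonic_fraction,
              n_expr_samples = as.integer(n_expr_samples),
              expr_noise_sdlog = expr_noise_sdlog,
              gb_hmc_prob = gb_hmc_prob,
              background_hmc_prob = background_hmc_prob,
              nonconv_5mC = nonconv_5mC, nonconv_C = nonconv_C,
              protection_rate = protection_rate,
              coverage = coverage, spikein_coverage = spikein_coverage,
              lambda_length = as.integer(lambda_length),
              puc19_length = as.integer(puc19_length),
              flank_bin_size = as.integer(flank_bin_size))
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths < 1000))
    stop_validation("'chrom_lengths' must be named and at least 1 kb each")
  probs <- c(cfg$gb_hmc_prob, cfg$background_hmc_prob, cfg$nonconv_5mC,
             cfg$nonconv_C, cfg$protection_rate, cfg$gc_content)
  if (any(probs < 0 | probs > 1))
    stop_validation("all probabilities must lie in [0, 1]")
  if (length(cfg$gb_hmc_prob) != 5L)
    stop_validation("'gb_hmc_prob' needs one value per quintile (5)")
  if (cfg$coverage <= 0 || cfg$spikein_coverage <= 0)
    stop_validation("coverages must be positive")
  if (cfg$n_genes < 5L) stop_validation("need at least 5 genes")
  mean_len <- exp(cfg$gene_length_meanlog + cfg$gene_length_sdlog^2 / 2)
  if (cfg$gene_length_max > min(cfg$chrom_lengths) ||
      mean_len * cfg$n_genes > 0.85 * sum(cfg$chrom_lengths))
    stop_validation("genes cannot fit on the configured chromosomes")
  structure(cfg, class = "sim_config")
}

# All cytosine positions (both strands) of a chromosome string, with the
# strand-aware dinucleotide/trinucleotide context. Near the contig edge the
# context falls back to CHH/CHG on the available bases.
find_cytosine_sites <- function(seqstr) {
  ch <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ip <- which(ch == "C")                       # plus-strand cytosines
  nxt1 <- ifelse(ip + 1L <= n, ch[ip + 1L], "")
  nxt2 <- ifelse(ip + 2L <= n, ch[ip + 2L], "")
  ctx_p <- ifelse(nxt1 == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
  im <- which(ch == "G")                       # minus-strand cytosines
  prv1 <- ifelse(im >= 2L, ch[pmax(im - 1L, 1L)], "")
  prv2 <- ifelse(im >= 3L, ch[pmax(im - 2L, 1L)], "")
  ctx_m <- ifelse(prv1 == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
  data.frame(pos = c(ip, im) - 1L,
             strand = rep(c("+", "-"), c(length(ip), length(im))),
             context = c(ctx_p, ctx_m), stringsAsFactors = FALSE)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Draw per-site coverage and protected counts; drop uncovered sites.
draw_calls <- function(sites, prob, coverage) {
  total <- rpois(nrow(sites), coverage)
  protected <- rbinom(nrow(sites), total, prob)
  keep <- total > 0L
  cbind(sites[keep, , drop = FALSE],
        data.frame(protected = protected[keep], total = total[keep]))
}

#' Simulate an expression table with known quintile truth
#'
#' Builds quintile labels with the same partition rule as
#' [assign_quintiles()] (extras to the lowest quintiles), places each gene's
#' exon-normalised mean score in a disjoint per-quintile band, and draws
#' per-sample values as `score x exonic_length x noise`, rescaled so the
#' per-gene sample mean divided by exonic length reproduces the target score
#' exactly. Re-running the quintile assignment on the emitted table therefore
#' recovers the configured labels without error.
#'
#' @param config a [sim_config()].
#' @param genes a [gene_models()] table.
#' @return data.frame (`gene_id` + one column per pseudo-sample) with
#'   attributes `quintile_truth` (named integer vector) and `scores`
#'   (named numeric vector of exon-normalised means).
#' @export
make_expression <- function(config, genes) {
  if (!inherits(config, "sim_config")) stop_validation("'config' must be a sim_config")
  n <- nrow(genes)
  if (n < 5L) stop_validation("need at least 5 genes")
  with_seed(config$seed + 1L, {
    sizes <- quintile_sizes(n)
    truth <- integer(n)
    truth[sample.int(n)] <- rep.int(1:5, sizes)
    score <- truth + runif(n, 0.05, 0.95)      # disjoint bands, no ties
    eps <- matrix(rlnorm(n * config$n_expr_samples, 0, config$expr_noise_sdlog),
                  nrow = n)
    eps <- eps / rowMeans(eps)                 # per-gene mean exactly 1
    vals <- score * genes$exonic_length * eps
    out <- data.frame(gene_id = genes$gene_id, vals, stringsAsFactors = FALSE)
    names(out) <- c("gene_id", sprintf("sample%02d", seq_len(config$n_expr_samples)))
    structure(out,
              quintile_truth = setNames(truth, genes$gene_id),
              scores = setNames(score, genes$gene_id))
  })
}

place_genes <- function(config) {
  n <- config$n_genes
  lens <- pmin(pmax(round(rlnorm(n, config$gene_length_meanlog,
                                 config$gene_length_sdlog)),
                    config$gene_length_min), config$gene_length_max)
  chroms <- names(config$chrom_lengths)
  chrom_of <- rep(chroms, length.out = n)[sample.int(n)]
  out <- vector("list", length(chroms))
  for (j in seq_along(chroms)) {
    idx <- which(chrom_of == chroms[j])
    if (!length(idx)) next
    l <- lens[idx]
    leftover <- as.numeric(config$chrom_lengths[j]) - sum(l)
    if (leftover <= length(idx))
      stop_validation("genes do not fit on chromosome ", chroms[j])
    gaps <- diff(c(0, sort(runif(length(idx), 0, leftover))))
    starts <- round(cumsum(gaps) + cumsum(c(0, l[-length(l)])))
    out[[j]] <- data.frame(chrom = chroms[j], start = as.integer(starts),
                           end = as.integer(starts + l), stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, out)
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  exfr <- runif(nrow(g), config$exonic_fraction[1L], config$exonic_fraction[2L])
  g$exonic_length <- pmax(2L, as.integer(round(exfr * (g$end - g$start))))
  g$gene_id <- sprintf("gene%04d", seq_len(nrow(g)))
  gene_models(g[c("gene_id", "chrom", "strand", "start", "end", "exonic_length")])
}

#' Simulate a complete synthetic TAB-seq dataset
#'
#' Generates, deterministically for a given config and seed: a toy genome,
#' non-overlapping gene models, an expression matrix with known quintile
#' truth ([make_expression()]), read-level call tables for the genomic
#' sample and for fully-5mC lambda and fully-5hmC pUC19 spike-ins, and a
#' truth set for every estimator in the pipeline. Per-site coverage is
#' Poisson at the configured depth and protected counts are binomial at the
#' site's per-read protected-call probability (see [sim_config()]).
#'
#' @param config a [sim_config()].
#' @return list of class `"tabseq_sim"` with elements `genome`
#'   (named character vector of sequences, incl. spike-ins), `genes`,
#'   `expression`, `calls`, `lambda_calls`, `puc19_calls`, `truth`
#'   (list: `rates`, `quintile` per gene, `scores`, `site_prob` for genomic
#'   CG sites, `n_reference_cytosines`, `coverage`) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1,
#'   chrom_lengths = c(chrA = 40000L), n_genes = 8, coverage = 2))
#' estimate_protection_rate(sim$puc19_calls)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop_validation("'config' must be a sim_config")
  genome <- with_seed(config$seed, {
    vapply(config$chrom_lengths, function(L) random_dna(L, config$gc_content), "")
  })
  genes <- with_seed(config$seed + 2L, place_genes(config))
  expr <- make_expression(config, genes)
  truth_q <- attr(expr, "quintile_truth")

  sites <- do.call(rbind, lapply(names(genome), function(chr) {
    s <- find_cytosine_sites(genome[[chr]])
    cbind(data.frame(chrom = chr, stringsAsFactors = FALSE), s)
  }))
  n_ref <- nrow(sites)

  # per-site protected-call probability
  prob <- ifelse(sites$context == "CG", config$background_hmc_prob, config$nonconv_C)
  cg <- which(sites$context == "CG")
  site_gr <- GenomicRanges::GRanges(sites$chrom[cg],
                                    IRanges::IRanges(sites$pos[cg] + 1L, width = 1L))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  qidx <- truth_q[genes$gene_id[S4Vectors::subjectHits(hits)]]
  prob[cg[S4Vectors::queryHits(hits)]] <- config$gb_hmc_prob[qidx]

  calls_df <- with_seed(config$seed + 3L, draw_calls(sites, prob, config$coverage))
  calls <- call_table(calls_df, sample_id = "synthetic", source_kind = "genome")

  spike <- with_seed(config$seed + 4L, {
    lam_seq <- random_dna(config$lambda_length, 0.5)
    puc_seq <- random_dna(config$puc19_length, 0.5)
    lam_sites <- cbind(data.frame(chrom = "lambda", stringsAsFactors = FALSE),
                       find_cytosine_sites(lam_seq))
    puc_sites <- cbind(data.frame(chrom = "pUC19", stringsAsFactors = FALSE),
                       find_cytosine_sites(puc_seq))
    lam_prob <- ifelse(lam_sites$context == "CG", config$nonconv_5mC, config$nonconv_C)
    puc_prob <- ifelse(puc_sites$context == "CG", config$protection_rate, config$nonconv_C)
    list(lam_seq = lam_seq, puc_seq = puc_seq,
         lam = draw_calls(lam_sites, lam_prob, config$spikein_coverage),
         puc = draw_calls(puc_sites, puc_prob, config$spikein_coverage))
  })
  lambda_calls <- call_table(spike$lam, sample_id = "lambda_spikein",
                             source_kind = "lambda_5mC")
  puc19_calls <- call_table(spike$puc, sample_id = "pUC19_spikein",
                            source_kind = "pUC19_5hmC")

  structure(list(
    genome = c(genome, lambda = spike$lam_seq, pUC19 = spike$puc_seq),
    genes = genes,
    expression = expr,
    calls = calls,
    lambda_calls = lambda_calls,
    puc19_calls = puc19_calls,
    truth = list(
      rates = c(nonconv_5mC = config$nonconv_5mC, nonconv_C = config$nonconv_C,
                protection_rate = config$protection_rate),
      quintile = truth_q,
      scores = attr(expr, "scores"),
      site_prob = data.frame(chrom = sites$chrom[cg], pos = sites$pos[cg],
                             strand = sites$strand[cg], prob = prob[cg],
                             stringsAsFactors = FALSE),
      n_reference_cytosines = n_ref,
      coverage = config$coverage),
    config = config), class = "tabseq_sim")
}

#' @export
print.tabseq_sim <- function(x, ...) {
  cat(sprintf(paste0("<tabseq_sim> seed %d: %d contigs (%s bp) + spike-ins, ",
                     "%d genes, %dx coverage\n"),
              x$config$seed, length(x$config$chrom_lengths),
              format(sum(x$config$chrom_lengths), big.mark = ","),
              nrow(x$genes), x$config$coverage))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa` (genome plus spike-in sequences), `genes.bed` (BED12),
#' `expression.tsv`, the three allc-style call tables, and truth files
#' (`truth_genes.tsv`, `truth_rates.json`).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param force overwrite existing files?
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE) {
  if (!inherits(sim, "tabseq_sim")) stop_validation("'sim' must be a tabseq_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genome.fa", "genes.bed", "expression.tsv",
                            "calls_genome.tsv", "calls_lambda.tsv",
                            "calls_puc19.tsv", "truth_genes.tsv",
                            "truth_rates.json"))
  if (!force && any(file.exists(paths)))
    stop_validation("output files exist in '", dir, "' (use force = TRUE)")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(sim$genome)),
                              paths[1L])
  write_gene_models(sim$genes, paths[2L], format = "bed")
  write.table(sim$expression, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  write_calls(sim$calls, paths[4L])
  write_calls(sim$lambda_calls, paths[5L])
  write_calls(sim$puc19_calls, paths[6L])
  tg <- data.frame(gene_id = names(sim$truth$quintile),
                   quintile = unname(sim$truth$quintile),
                   score = unname(sim$truth$scores))
  write.table(tg, paths[7L], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(as.list(sim$truth$rates),
                         list(coverage = sim$truth$coverage,
                              n_reference_cytosines = sim$truth$n_reference_cytosines)),
                       paths[8L], auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
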