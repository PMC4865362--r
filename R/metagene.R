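#' Gene-region bin scheme
#'
#' Each gene contributes 60 genomic intervals, ordered 5' to 3' of the gene:
#' 20 flank bins upstream of the TSS (`UTSS`), 20 bins evenly dividing the
#' gene body from TSS to TTS (`GB`), and 20 flank bins downstream of the TTS
#' (`DTTS`). Flank bins have a fixed width (default 5 kb, i.e. 100 kb spanned
#' in each direction); body bin `k` of a gene of length `L` covers
#' `[floor(kL/20), floor((k+1)L/20))` from the TSS, so the 20 bins tile the
#' body exactly for any `L >= 20`. For minus-strand genes the bins are
#' mirrored so that `UTSS` bin 0 is always farthest upstream in the gene's
#' own orientation. Flank bins running off a contig edge are clipped and
#' flagged, never dropped; flanks overlapping neighbouring genes are not
#' masked.
#'
#' @param gene single row of a [gene_models()] table (or a list with fields
#'   `gene_id`, `chrom`, `strand`, `start`, `end`).
#' @param n_flank_bins,n_body_bins number of bins per region (default 20).
#' @param flank_bin_size flank bin width in bp (default 5000).
#' @param chrom_length contig length for right-edge clipping, or `NULL`.
#' @return data.frame with one row per bin: `gene_id`, `chrom`, `region`
#'   (`UTSS`/`GB`/`DTTS`), `bin` (0-based, gene orientation), `start`, `end`
#'   (0-based half-open) and `clipped`. `NULL` (with a message) for genes
#'   shorter than `n_body_bins`.
#' @export
build_gene_bins <- function(gene, n_flank_bins = 20L, flank_bin_size = 5000L,
                            n_body_bins = 20L, chrom_length = NULL) {
  g <- as.data.frame(gene)[1L, , drop = FALSE]
  lens <- if (is.null(chrom_length)) NULL else setNames(chrom_length, g$chrom)
  bins <- build_bins_all(g, n_flank_bins = n_flank_bins,
                         flank_bin_size = flank_bin_size,
                         n_body_bins = n_body_bins, chrom_lengths = lens)
  if (nrow(bins) == 0L) {
    message("gene '", g$gene_id, "' shorter than ", n_body_bins, " bp: skipped")
    return(NULL)
  }
  bins
}

# Vectorised bin construction for a whole gene-model table. Genes shorter
# than n_body_bins are silently dropped here; callers report the count.
build_bins_all <- function(genes, n_flank_bins = 20L, flank_bin_size = 5000L,
                           n_body_bins = 20L, chrom_lengths = NULL) {
  nb <- as.integer(n_body_bins); nf <- as.integer(n_flank_bins)
  B <- as.numeric(flank_bin_size)
  if (nb < 1L || nf < 1L || B < 1) stop_validation("bin scheme parameters must be positive")
  genes <- as.data.frame(genes)
  genes <- genes[(genes$end - genes$start) >= nb, , drop = FALSE]
  ng <- nrow(genes)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      region = character(), bin = integer(),
                      start = numeric(), end = numeric(), clipped = logical())
  if (ng == 0L) return(empty)

  gi_b <- rep(seq_len(ng), each = nb)   # body bin expansion
  kb <- rep.int(seq_len(nb) - 1, ng)
  gi_f <- rep(seq_len(ng), each = nf)   # flank bin expansion
  kf <- rep.int(seq_len(nf) - 1, ng)
  start_b <- as.numeric(genes$start)[gi_b]; end_b <- as.numeric(genes$end)[gi_b]
  start_f <- as.numeric(genes$start)[gi_f]; end_f <- as.numeric(genes$end)[gi_f]
  L <- end_b - start_b
  plus_b <- (genes$strand == "+")[gi_b]
  plus_f <- (genes$strand == "+")[gi_f]

  # upstream flank: bin 0 farthest 5' of the TSS
  up_s <- ifelse(plus_f, start_f - (nf - kf) * B, end_f + (nf - 1 - kf) * B)
  up_e <- ifelse(plus_f, start_f - (nf - 1 - kf) * B, end_f + (nf - kf) * B)
  # gene body: floor-rule partition of [start, end)
  bd_s <- ifelse(plus_b, start_b + floor(kb * L / nb), end_b - floor((kb + 1) * L / nb))
  bd_e <- ifelse(plus_b, start_b + floor((kb + 1) * L / nb), end_b - floor(kb * L / nb))
  # downstream flank: bin 0 adjacent to the TTS
  dn_s <- ifelse(plus_f, end_f + kf * B, start_f - (kf + 1) * B)
  dn_e <- ifelse(plus_f, end_f + (kf + 1) * B, start_f - kf * B)

  out <- data.frame(
    gene_id = c(genes$gene_id[gi_f], genes$gene_id[gi_b], genes$gene_id[gi_f]),
    chrom = c(genes$chrom[gi_f], genes$chrom[gi_b], genes$chrom[gi_f]),
    region = rep(c("UTSS", "GB", "DTTS"), c(ng * nf, ng * nb, ng * nf)),
    bin = c(kf, kb, kf),
    start = c(up_s, bd_s, dn_s),
    end = c(up_e, bd_e, dn_e),
    stringsAsFactors = FALSE)

  raw_s <- out$start; raw_e <- out$end
  out$start <- pmax(out$start, 0)
  out$end <- pmax(out$end, out$start)
  if (!is.null(chrom_lengths)) {
    len <- as.numeric(chrom_lengths[out$chrom])
    known <- !is.na(len)
    out$end[known] <- pmin(out$end[known], len[known])
    out$start[known] <- pmin(out$start[known], out$end[known])
  }
  out$clipped <- out$start != raw_s | out$end != raw_e
  # 5'->3' presentation order per gene: UTSS 0..19, GB, DTTS
  ord <- order(match(out$gene_id, genes$gene_id),
               match(out$region, c("UTSS", "GB", "DTTS")), out$bin,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted 5hmCG level of a genomic interval
#'
#' Pools the CG-context calls of both strands inside the half-open interval
#' and returns the read-weighted level: summed protected reads over summed
#' coverage — never the mean of per-site ratios. An interval with no covered
#' CG yields a missing level, not 0.
#'
#' @param calls a [call_table()].
#' @param chrom,start,end half-open 0-based interval.
#' @return list with `protected`, `total` and `level`
#'   (`NA` when `total == 0`).
#' @examples
#' ct <- call_table(data.frame(chrom = "c", pos = c(1L, 5L), strand = "+",
#'                             context = "CG", protected = c(1L, 1L),
#'                             total = c(2L, 18L)))
#' weighted_level(ct, "c", 0, 10)   # 2/20 = 0.10, not mean(0.5, 1/18)
#' @export
weighted_level <- function(calls, chrom, start, end) {
  if (!inherits(calls, "call_table")) stop_validation("'calls' must be a call_table")
  keep <- calls$context == "CG" & calls$chrom == chrom &
    calls$pos >= start & calls$pos < end
  prot <- sum(as.numeric(calls$protected[keep]))
  tot <- sum(as.numeric(calls$total[keep]))
  list(protected = prot, total = tot,
       level = if (tot > 0) prot / tot else NA_real_)
}

#' Metagene 5hmCG profiles per expression quintile
#'
#' For every quintile and each of the 60 gene-region bins (see
#' [build_gene_bins()]), counts are pooled across all member genes before
#' dividing, i.e. the quintile bin level is the read-weighted level of the
#' pooled counts. A gene-averaged variant (mean of per-gene bin levels) is
#' available via `gene_average = TRUE`.
#'
#' @param calls genomic [call_table()].
#' @param genes a [gene_models()] table.
#' @param assignment a [assign_quintiles()] result covering the gene set.
#' @param n_flank_bins,flank_bin_size,n_body_bins bin scheme parameters
#'   (defaults 20 bins, 5 kb flank bins, 20 body bins).
#' @param chrom_lengths optional named vector of contig lengths for edge
#'   clipping.
#' @param gene_average average per-gene levels instead of pooling counts.
#' @param scale optional protection rate; when given, levels are divided by
#'   it (counts are reported raw either way).
#' @return data.frame of class `"metagene_profile"`: one row per
#'   (quintile, region, bin) with `sample_id`, `quintile`, `region`, `bin`,
#'   `protected`, `total`, `level` (`NA` where `total == 0`) and `n_genes`
#'   (genes contributing coverage to the bin).
#' @export
compute_metagene <- function(calls, genes, assignment,
                             n_flank_bins = 20L, flank_bin_size = 5000L,
                             n_body_bins = 20L, chrom_lengths = NULL,
                             gene_average = FALSE, scale = NULL) {
  if (!inherits(calls, "call_table")) stop_validation("'calls' must be a call_table")
  if (!inherits(assignment, "quintile_assignment"))
    stop_validation("'assignment' must be a quintile_assignment")
  genes <- as.data.frame(genes)
  genes <- genes[genes$gene_id %in% assignment$gene_id, , drop = FALSE]
  if (!nrow(genes)) stop_validation("no annotated genes in the assignment")
  quint <- assignment$quintile[match(genes$gene_id, assignment$gene_id)]

  n_short <- sum((genes$end - genes$start) < n_body_bins)
  if (n_short) message(n_short, " gene(s) shorter than ", n_body_bins, " bp skipped")
  bins <- build_bins_all(genes, n_flank_bins = n_flank_bins,
                         flank_bin_size = flank_bin_size,
                         n_body_bins = n_body_bins, chrom_lengths = chrom_lengths)
  nb <- as.integer(n_body_bins); nf <- as.integer(n_flank_bins)
  regions <- c("UTSS", "GB", "DTTS")
  sizes <- c(UTSS = nf, GB = nb, DTTS = nf)
  offset <- c(UTSS = 0L, GB = nf, DTTS = nf + nb)
  S <- nf + nb + nf
  grid <- data.frame(
    quintile = rep(1:5, each = S),
    region = rep(rep(regions, times = sizes), 5L),
    bin = rep(c(seq_len(nf) - 1L, seq_len(nb) - 1L, seq_len(nf) - 1L), 5L),
    stringsAsFactors = FALSE)
  gid_of <- function(q, r, b) (q - 1L) * S + offset[r] + b + 1L
  grid$gid <- unname(gid_of(grid$quintile, grid$region, grid$bin))

  prot <- tot <- numeric(nrow(grid))
  n_genes <- integer(nrow(grid))
  cg <- calls$context == "CG"
  if (nrow(bins) && any(cg)) {
    bins$quintile <- quint[match(bins$gene_id, genes$gene_id)]
    bins$gid <- gid_of(bins$quintile, bins$region, bins$bin)
    nonempty <- bins$end > bins$start
    bg <- GenomicRanges::GRanges(bins$chrom[nonempty],
                                 IRanges::IRanges(start = bins$start[nonempty] + 1,
                                                  end = bins$end[nonempty]))
    cgc <- which(cg)
    qg <- GenomicRanges::GRanges(calls$chrom[cgc],
                                 IRanges::IRanges(start = calls$pos[cgc] + 1, width = 1L))
    hits <- GenomicRanges::findOverlaps(qg, bg)
    ci <- cgc[S4Vectors::queryHits(hits)]
    bi <- which(nonempty)[S4Vectors::subjectHits(hits)]
    if (length(ci)) {
      cp <- as.numeric(calls$protected[ci]); ctot <- as.numeric(calls$total[ci])
      # per gene-bin row first (for n_genes and the gene-averaged variant)
      br_tot <- rowsum(ctot, bi); br_prot <- rowsum(cp, bi)
      br_idx <- as.integer(rownames(br_tot))
      covered <- br_tot[, 1L] > 0
      n_genes <- as.integer(tabulate(bins$gid[br_idx[covered]], nbins = nrow(grid)))
      if (gene_average) {
        lev_br <- br_prot[covered, 1L] / br_tot[covered, 1L]
        s <- rowsum(lev_br, bins$gid[br_idx[covered]])
        gidx <- as.integer(rownames(s))
        prot[gidx] <- NA  # per-gene averaging has no pooled-count meaning
        tot[gidx] <- NA
        lev <- rep(NA_real_, nrow(grid))
        lev[gidx] <- s[, 1L] / n_genes[gidx]
      } else {
        s <- rowsum(cbind(cp, ctot), bins$gid[bi])
        gidx <- as.integer(rownames(s))
        prot[gidx] <- s[, 1L]; tot[gidx] <- s[, 2L]
      }
    }
  }
  out <- grid[c("quintile", "region", "bin")]
  out$protected <- prot
  out$total <- tot
  out$level <- if (gene_average && exists("lev", inherits = FALSE)) lev
               else ifelse(!is.na(tot) & tot > 0, prot / tot, NA_real_)
  if (!is.null(scale)) {
    if (!is.numeric(scale) || scale <= 0 || scale > 1)
      stop_validation("'scale' must be a protection rate in (0, 1]")
    out$level <- out$level / scale
  }
  out$n_genes <- n_genes
  out <- cbind(sample_id = sample_id(calls), out, stringsAsFactors = FALSE)
  for (q in 1:5)
    if (all(is.na(out$level[out$quintile == q])))
      warning("quintile ", q, " has no covered bins", call. = FALSE)
  rownames(out) <- NULL
  structure(out,
            params = list(n_flank_bins = n_flank_bins,
                          flank_bin_size = flank_bin_size,
                          n_body_bins = n_body_bins,
                          gene_average = gene_average),
            class = c("metagene_profile", "data.frame"))
}

#' Plot a metagene profile
#'
#' One line per quintile over the 60 ordered bins, with the upstream flank,
#' gene body and downstream flank panels separated by vertical lines —
#' the standard metagene layout.
#'
#' @param x a `"metagene_profile"`.
#' @param ... passed to [graphics::matplot()].
#' @method plot metagene_profile
#' @export
plot.metagene_profile <- function(x, ...) {
  p <- attr(x, "params")
  nb <- p$n_body_bins; nf <- p$n_flank_bins
  ord <- order(x$quintile, match(x$region, c("UTSS", "GB", "DTTS")), x$bin)
  x <- x[ord, ]
  m <- matrix(x$level, ncol = 5L,
              dimnames = list(NULL, paste0("Q", 1:5)))
  matplot(seq_len(nrow(m)), m, type = "l", lty = 1L, lwd = 2L,
          xlab = "", ylab = "weighted 5hmCG level", xaxt = "n", ...)
  abline(v = c(nf, nf + nb) + 0.5, lty = 2L, col = "grey50")
  axis(1, at = c(nf / 2, nf + nb / 2, nf + nb + nf / 2),
       labels = c("UTSS", "GB", "DTTS"), tick = FALSE)
  legend("topleft", legend = paste("quintile", 1:5), col = 1:5, lty = 1L,
         lwd = 2L, bty = "n", cex = 0.8)
  invisible(x)
}

#' Binomial subsampling of a call table
#'
#' Emulates sequencing at a lower depth: each original read is retained
#' independently with probability `fraction`, so each site's coverage is
#' binomially thinned and, given the new coverage, the protected count
#' follows the hypergeometric draw from the site's original reads. Sites
#' whose coverage reaches 0 are removed. The coverage of the output is
#' `fraction` times the input coverage in expectation.
#'
#' @param calls a [call_table()].
#' @param fraction retention probability in (0, 1]. No upsampling.
#' @param seed mandatory RNG seed (the caller's RNG stream is untouched).
#' @return a thinned [call_table()].
#' @export
subsample_calls <- function(calls, fraction, seed) {
  if (!inherits(calls, "call_table")) stop_validation("'calls' must be a call_table")
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1)
    stop_validation("'fraction' must lie in (0, 1]")
  if (missing(seed)) stop_validation("'seed' is required")
  if (fraction == 1) return(calls)
  with_seed(seed, {
    n <- nrow(calls)
    new_tot <- rbinom(n, calls$total, fraction)
    new_prot <- rhyper(n, m = calls$protected, n = calls$total - calls$protected,
                       k = new_tot)
    keep <- new_tot > 0L
    df <- as.data.frame(calls)[keep, , drop = FALSE]
    df$total <- new_tot[keep]
    df$protected <- new_prot[keep]
    call_table(df, sample_id = sample_id(calls), source_kind = source_kind(calls))
  })
}
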