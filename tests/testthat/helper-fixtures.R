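# Small in-code fixtures shared across the suite.

# Quick call-table builder: one row per site.
make_ct <- function(pos, protected, total, context = "CG", strand = "+",
                    chrom = "chr1", sample_id = "s", source_kind = "genome") {
  call_table(data.frame(chrom = chrom, pos = as.integer(pos),
                        strand = strand, context = context,
                        protected = as.integer(protected),
                        total = as.integer(total),
                        stringsAsFactors = FALSE),
             sample_id = sample_id, source_kind = source_kind)
}

# A call table whose pooled CG counts equal (protected, total) split over two
# sites, for reproducing printed global-percentage rows.
ct_with_counts <- function(protected, total, sample_id = "s") {
  p1 <- protected %/% 2L
  t1 <- total %/% 2L
  make_ct(pos = c(10L, 20L), protected = c(p1, protected - p1),
          total = c(t1, total - t1), sample_id = sample_id)
}

# Tiny 5-gene model set on a 100 kb contig, both strands.
toy_genes <- function() {
  gene_models(data.frame(
    gene_id = paste0("g", 1:5),
    chrom = "chr1",
    strand = c("+", "-", "+", "-", "+"),
    start = c(1000L, 8000L, 20000L, 45000L, 70000L),
    end = c(3000L, 12000L, 20500L, 52000L, 79000L),
    exonic_length = c(1500L, 3000L, 400L, 5000L, 9000L)))
}

# Small simulation config used where full scale is not needed.
small_cfg <- function(seed, spikein_coverage = 20, ...) {
  sim_config(seed = seed, chrom_lengths = c(chrA = 30000L, chrB = 30000L),
             n_genes = 10L, gene_length_meanlog = log(1500),
             gene_length_sdlog = 0.3, gene_length_min = 300L,
             gene_length_max = 4000L, flank_bin_size = 50L,
             spikein_coverage = spikein_coverage, ...)
}

# Run the command-line entry point in a fresh R process against the
# installed package; returns list(status, stdout+stderr lines).
run_cli <- function(args) {
  script <- system.file("cli", "hydroxymeta.R", package = "hydroxymeta")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = as.character(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
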