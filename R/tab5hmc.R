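#' Fit the full TAB-seq 5hmC analysis for one sample
#'
#' One-call interface tying the pipeline stages together: spike-in
#' calibration ([calibrate_sample()]), global raw and protection-scaled
#' %5hmCG ([global_5hmCG()], [scale_pct()]), exon-length-normalised
#' expression quintiles ([normalize_expression()], [assign_quintiles()]) and
#' per-quintile metagene profiles ([compute_metagene()]).
#'
#' @param genome_calls genomic [call_table()].
#' @param genes a [gene_models()] table.
#' @param expression expression table ([read_expression()] layout).
#' @param lambda_calls,puc19_calls optional spike-in call tables; without
#'   the pUC19 control the scaled %5hmCG is left missing.
#' @param n_flank_bins,flank_bin_size,n_body_bins,chrom_lengths,gene_average
#'   passed to [compute_metagene()].
#' @param n_reference_cytosines optional; when given, sequencing coverage in
#'   genome equivalents is reported ([estimate_coverage()]).
#' @return object of class `"tab5hmc"`: list with `sample_id`, `rates`,
#'   `global`, `assignment`, `profile`, `coverage` and `params`. Methods:
#'   `print`, `summary`, `coef` (the three calibration rates), `plot`
#'   (metagene profile).
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7,
#'   chrom_lengths = c(chrA = 60000L), n_genes = 10, coverage = 3))
#' fit <- tab5hmc(sim$calls, sim$genes, sim$expression,
#'                lambda_calls = sim$lambda_calls,
#'                puc19_calls = sim$puc19_calls,
#'                flank_bin_size = 100,
#'                n_reference_cytosines = sim$truth$n_reference_cytosines)
#' fit
#' coef(fit)
#' @export
tab5hmc <- function(genome_calls, genes, expression,
                    lambda_calls = NULL, puc19_calls = NULL,
                    n_flank_bins = 20L, flank_bin_size = 5000L,
                    n_body_bins = 20L, chrom_lengths = NULL,
                    gene_average = FALSE, n_reference_cytosines = NULL) {
  rates <- calibrate_sample(genome_calls, lambda_calls, puc19_calls)
  glob <- global_5hmCG(genome_calls)
  if (!is.null(rates$protection_rate)) glob <- scale_pct(glob, rates)
  scores <- normalize_expression(expression, genes)
  assignment <- assign_quintiles(scores)
  profile <- compute_metagene(genome_calls, genes, assignment,
                              n_flank_bins = n_flank_bins,
                              flank_bin_size = flank_bin_size,
                              n_body_bins = n_body_bins,
                              chrom_lengths = chrom_lengths,
                              gene_average = gene_average)
  coverage <- if (!is.null(n_reference_cytosines))
    estimate_coverage(genome_calls, n_reference_cytosines) else NA_real_
  structure(list(sample_id = sample_id(genome_calls),
                 rates = rates, global = glob,
                 assignment = assignment, profile = profile,
                 coverage = coverage,
                 params = list(n_flank_bins = n_flank_bins,
                               flank_bin_size = flank_bin_size,
                               n_body_bins = n_body_bins,
                               gene_average = gene_average)),
            class = "tab5hmc")
}

#' @export
print.tab5hmc <- function(x, ...) {
  cat(sprintf("TAB-seq 5hmC analysis of sample '%s'\n", x$sample_id))
  print(x$global)
  if (!is.na(x$coverage))
    cat(sprintf("Coverage: %.3f genome equivalents\n", x$coverage))
  print(x$assignment)
  invisible(x)
}

#' @method summary tab5hmc
#' @export
summary.tab5hmc <- function(object, ...) {
  x <- object
  print(x)
  print(x$rates)
  gb <- x$profile[x$profile$region == "GB", ]
  lev <- vapply(1:5, function(q) {
    rows <- gb$quintile == q & !is.na(gb$total)
    tot <- sum(gb$total[rows])
    if (tot > 0) sum(gb$protected[rows]) / tot else NA_real_
  }, numeric(1))
  cat("Pooled gene-body 5hmCG level by quintile (1 = lowest expression):\n")
  print(setNames(round(lev, 5), paste0("Q", 1:5)))
  if (!is.na(lev[1L]) && lev[1L] > 0)
    cat(sprintf("Q5/Q1 gene-body fold change: %.2f\n", lev[5L] / lev[1L]))
  invisible(x)
}

#' @method coef tab5hmc
#' @export
coef.tab5hmc <- function(object, ...) {
  get_rate <- function(r) if (is.null(r)) NA_real_ else r$rate
  c(nonconv_5mC = get_rate(object$rates$nonconv_5mC),
    nonconv_C = get_rate(object$rates$nonconv_C),
    protection_rate = get_rate(object$rates$protection_rate))
}

#' @method plot tab5hmc
#' @export
plot.tab5hmc <- function(x, ...) plot(x$profile, ...)
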