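#' Spike-in calibration rates
#'
#' TAB-seq reads a cytosine as C only when it was 5hmC and protected by
#' beta-glucosyltransferase, or when conversion failed. Three control rates
#' calibrate the assay, each a read-weighted pooled ratio
#' (sum of protected reads over sum of covering reads, never a mean of
#' per-site ratios):
#' \describe{
#'   \item{`estimate_nonconversion_5mC`}{fraction of reads at CG sites of the
#'     fully 5mC-methylated lambda spike-in still read as C — the 5mC
#'     non-conversion rate after Tet oxidation and bisulfite treatment.}
#'   \item{`estimate_nonconversion_C`}{fraction of reads at genomic non-CG
#'     (CHG/CHH) cytosines read as C — the non-conversion rate of unmodified
#'     cytosines.}
#'   \item{`estimate_protection_rate`}{fraction of reads at CG sites of the
#'     fully 5hmC pUC19 spike-in read as C — the protection rate, which
#'     divides raw %5hmCG to give the scaled estimate.}
#' }
#'
#' @param lambda_calls,genome_calls,puc19_calls [call_table()]s with the
#'   matching `source_kind`.
#' @return An object of class `"cal_rate"`: list with `rate`, supporting
#'   `protected` and `total` read counts, and `kind`. [confint()] gives the
#'   exact (Clopper-Pearson) binomial confidence interval.
#' @examples
#' lam <- call_table(data.frame(chrom = "lambda", pos = c(3L, 9L), strand = "+",
#'                              context = "CG", protected = c(2L, 1L),
#'                              total = c(10L, 10L)),
#'                   source_kind = "lambda_5mC")
#' estimate_nonconversion_5mC(lam)   # pooled 3/20 = 0.15
#' @name calibration
NULL

new_cal_rate <- function(protected, total, kind) {
  structure(list(rate = protected / total,
                 protected = as.numeric(protected), total = as.numeric(total),
                 kind = kind),
            class = "cal_rate")
}

pooled_rate <- function(calls, keep, kind, what) {
  calls <- filter_calls(calls, keep)
  tot <- sum(as.numeric(calls$total))
  if (nrow(calls) == 0L || tot == 0)
    stop_validation("rate undefined: no covered ", what, " sites")
  new_cal_rate(sum(as.numeric(calls$protected)), tot, kind)
}

#' @rdname calibration
#' @export
estimate_nonconversion_5mC <- function(lambda_calls) {
  if (!inherits(lambda_calls, "call_table"))
    stop_validation("'lambda_calls' must be a call_table")
  if (!identical(source_kind(lambda_calls), "lambda_5mC"))
    stop_validation("'lambda_calls' must have source_kind 'lambda_5mC'")
  pooled_rate(lambda_calls, lambda_calls$context == "CG",
              "nonconv_5mC", "lambda CG")
}

#' @rdname calibration
#' @export
estimate_nonconversion_C <- function(genome_calls) {
  if (!inherits(genome_calls, "call_table"))
    stop_validation("'genome_calls' must be a call_table")
  pooled_rate(genome_calls, genome_calls$context %in% c("CHG", "CHH"),
              "nonconv_C", "non-CG")
}

#' @rdname calibration
#' @export
estimate_protection_rate <- function(puc19_calls) {
  if (!inherits(puc19_calls, "call_table"))
    stop_validation("'puc19_calls' must be a call_table")
  if (!identical(source_kind(puc19_calls), "pUC19_5hmC"))
    stop_validation("'puc19_calls' must have source_kind 'pUC19_5hmC'")
  pooled_rate(puc19_calls, puc19_calls$context == "CG",
              "protection_rate", "pUC19 CG")
}

#' @export
print.cal_rate <- function(x, ...) {
  cat(sprintf("<cal_rate> %s = %.5f (%s / %s reads)\n", x$kind, x$rate,
              format(x$protected, big.mark = ","), format(x$total, big.mark = ",")))
  invisible(x)
}

#' @method confint cal_rate
#' @export
confint.cal_rate <- function(object, parm, level = 0.99, ...) {
  ci <- stats::binom.test(round(object$protected), round(object$total),
                          conf.level = level)$conf.int
  m <- matrix(ci, 1L, dimnames = list(object$kind, c("lower", "upper")))
  attr(m, "conf.level") <- level
  m
}

#' Estimate all calibration rates for one sample
#'
#' @param genome_calls genomic [call_table()] (supplies non-CG sites).
#' @param lambda_calls fully-5mC lambda spike-in calls, or `NULL`.
#' @param puc19_calls fully-5hmC pUC19 spike-in calls, or `NULL`.
#' @return class `"calibration_rates"`: list with elements `nonconv_5mC`,
#'   `nonconv_C`, `protection_rate` (each a `cal_rate` or `NULL`) and
#'   `sample_id`. Rates are per sample, never pooled across samples.
#' @export
calibrate_sample <- function(genome_calls, lambda_calls = NULL, puc19_calls = NULL) {
  structure(list(
    sample_id = sample_id(genome_calls),
    nonconv_5mC = if (!is.null(lambda_calls)) estimate_nonconversion_5mC(lambda_calls),
    nonconv_C = estimate_nonconversion_C(genome_calls),
    protection_rate = if (!is.null(puc19_calls)) estimate_protection_rate(puc19_calls)),
    class = "calibration_rates")
}

#' @export
print.calibration_rates <- function(x, ...) {
  cat(sprintf("Calibration rates for sample '%s'\n", x$sample_id))
  for (nm in c("nonconv_5mC", "nonconv_C", "protection_rate"))
    if (!is.null(x[[nm]])) print(x[[nm]]) else cat(sprintf("<cal_rate> %s: not estimated\n", nm))
  invisible(x)
}

#' Global weighted 5hmCG level of a sample
#'
#' Pools all CG-context calls of the sample: `total_5hmCG` is the summed
#' protected read count, `total_CG` the summed read coverage, and
#' `pct_5hmCG = 100 * total_5hmCG / total_CG`. Display uses two decimals
#' (half-even); full precision is kept internally.
#'
#' @param genome_calls a [call_table()].
#' @return class `"global_level"`: list with `sample_id`, `total_5hmCG`,
#'   `total_CG`, `pct_5hmCG`, and (after [scale_pct()]) `scaled_pct` and
#'   `protection_rate`.
#' @export
global_5hmCG <- function(genome_calls) {
  if (!inherits(genome_calls, "call_table"))
    stop_validation("'genome_calls' must be a call_table")
  cg <- filter_calls(genome_calls, genome_calls$context == "CG")
  tot <- sum(as.numeric(cg$total))
  if (nrow(cg) == 0L || tot == 0)
    stop_validation("global %5hmCG undefined: no covered CG sites")
  prot <- sum(as.numeric(cg$protected))
  structure(list(sample_id = sample_id(genome_calls),
                 total_5hmCG = prot, total_CG = tot,
                 pct_5hmCG = 100 * prot / tot,
                 scaled_pct = NA_real_, protection_rate = NA_real_),
            class = "global_level")
}

#' Scale a global %5hmCG by the spike-in protection rate
#'
#' The scaled value `pct_5hmCG / protection_rate` estimates the true genomic
#' 5hmCG percentage, correcting for incomplete protection in the assay.
#'
#' @param level a `"global_level"` from [global_5hmCG()].
#' @param rates a [calibrate_sample()] result, a `cal_rate`, or a number in
#'   (0, 1].
#' @return the `"global_level"` with `scaled_pct` and `protection_rate`
#'   filled. Values above 100 are capped at 100 with a warning.
#' @export
scale_pct <- function(level, rates) {
  if (!inherits(level, "global_level"))
    stop_validation("'level' must be a global_level")
  p <- if (inherits(rates, "calibration_rates")) {
    if (is.null(rates$protection_rate))
      stop_validation("no protection rate available in 'rates'")
    rates$protection_rate$rate
  } else if (inherits(rates, "cal_rate")) rates$rate
  else if (is.numeric(rates) && length(rates) == 1L) rates
  else stop_validation("'rates' must be calibration rates or a single number")
  if (is.na(p) || p <= 0 || p > 1)
    stop_validation("protection rate must lie in (0, 1], got ", p)
  s <- level$pct_5hmCG / p
  if (s > 100) {
    warning("scaled %5hmCG exceeds 100; capping", call. = FALSE)
    s <- 100
  }
  level$scaled_pct <- s
  level$protection_rate <- p
  level
}

#' @export
print.global_level <- function(x, ...) {
  cat(sprintf("Sample '%s': %s / %s reads -> %%5hmCG = %s",
              x$sample_id,
              format(x$total_5hmCG, big.mark = ","),
              format(x$total_CG, big.mark = ","),
              format_pct(x$pct_5hmCG)))
  if (!is.na(x$scaled_pct))
    cat(sprintf("; scaled %%5hmCG = %s (protection %.4f)",
                format_pct(x$scaled_pct), x$protection_rate))
  cat("\n")
  invisible(x)
}

#' Sequencing coverage in genome equivalents
#'
#' Mean read depth per reference cytosine: the summed read coverage of all
#' calls (any context, covered or not in the table) divided by the number of
#' cytosine sites in the reference, used as the genome-equivalents proxy.
#'
#' @param genome_calls a [call_table()].
#' @param n_reference_cytosines number of cytosine positions (both strands)
#'   in the reference the calls were made against.
#' @return coverage in genome equivalents (a single number).
#' @export
estimate_coverage <- function(genome_calls, n_reference_cytosines) {
  if (!inherits(genome_calls, "call_table"))
    stop_validation("'genome_calls' must be a call_table")
  if (!is_count(n_reference_cytosines) || n_reference_cytosines == 0)
    stop_validation("'n_reference_cytosines' must be a positive count")
  sum(as.numeric(genome_calls$total)) / n_reference_cytosines
}
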