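#' Chi-square comparison of two samples' global 5hmCG levels
#'
#' Pearson chi-square (df = 1, no continuity correction — counts here are of
#' order 1e5, where the correction is immaterial) on the 2x2 table of
#' protected vs converted read counts of the two samples. The statistic is
#' the closed form `sum((O - E)^2 / E)` and equals the square of the
#' two-proportion z statistic on the same counts.
#'
#' @param a,b `"global_level"` objects from [global_5hmCG()].
#' @return class `"population_comparison"`: list with `samples`, the 2x2
#'   `counts` matrix, `statistic`, `df`, `p_value` and `pct_diff`
#'   (raw percentage-point difference `a - b`). P-values are reported raw;
#'   multiple-testing correction is left to the caller.
#' @export
chi_square_global <- function(a, b) {
  for (x in list(a, b))
    if (!inherits(x, "global_level")) stop_validation("inputs must be global_level objects")
  O <- matrix(c(a$total_5hmCG, a$total_CG - a$total_5hmCG,
                b$total_5hmCG, b$total_CG - b$total_5hmCG),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c(a$sample_id, b$sample_id),
                              c("protected", "converted")))
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop_validation("degenerate 2x2 table: a margin is zero")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  structure(list(samples = rownames(O), counts = O,
                 statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
                 pct_diff = a$pct_5hmCG - b$pct_5hmCG),
            class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf("Chi-square comparison %s vs %s\n", x$samples[1L], x$samples[2L]))
  print(x$counts)
  cat(sprintf("X-squared = %.4g, df = %d, p = %.4g; raw pct diff = %+.2f\n",
              x$statistic, x$df, x$p_value, x$pct_diff))
  invisible(x)
}

#' Gene-body 5hmCG fold change between expression quintiles
#'
#' Ratio of the read-pooled gene-body levels of two quintiles: counts of the
#' 20 GB bins are pooled per quintile before dividing. The fold is invariant
#' to protection-rate scaling, which cancels in the ratio.
#'
#' @param profile a [compute_metagene()] result containing both quintiles
#'   (or just the high quintile when `profile_low` is given).
#' @param profile_low optional second profile holding the low quintile, for
#'   the two-profile calling convention.
#' @param high,low quintiles to compare (defaults 5 = highest vs 1 = lowest).
#' @return the fold change (a single number).
#' @export
gene_body_fold_change <- function(profile, profile_low = NULL, high = 5L, low = 1L) {
  if (!inherits(profile, "metagene_profile"))
    stop_validation("'profile' must be a metagene_profile")
  lo_src <- if (is.null(profile_low)) profile else {
    if (!inherits(profile_low, "metagene_profile"))
      stop_validation("'profile_low' must be a metagene_profile")
    profile_low
  }
  pool <- function(p, q) {
    rows <- p$region == "GB" & p$quintile == q & !is.na(p$total)
    c(prot = sum(p$protected[rows]), tot = sum(p$total[rows]))
  }
  hi <- pool(profile, high); lo <- pool(lo_src, low)
  if (lo[["tot"]] == 0 || lo[["prot"]] == 0)
    stop_validation("fold change undefined: quintile ", low,
                    " gene-body level is zero or uncovered")
  if (hi[["tot"]] == 0)
    stop_validation("fold change undefined: quintile ", high, " gene body uncovered")
  (hi[["prot"]] / hi[["tot"]]) / (lo[["prot"]] / lo[["tot"]])
}
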