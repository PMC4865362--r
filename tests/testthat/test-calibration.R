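test_that("calibration rates are read-weighted pooled ratios, not site means", {
  # asymmetric two-site fixture: pooled 3/40 = 0.075, site mean would be 0.1167
  lam <- make_ct(pos = c(2L, 8L), protected = c(2L, 1L), total = c(10L, 30L),
                 source_kind = "lambda_5mC")
  r <- estimate_nonconversion_5mC(lam)
  expect_equal(r$rate, 3 / 40)
  expect_equal(c(r$protected, r$total), c(3, 40))
  # hand sum from equal-coverage sites: (2/10, 1/10) -> 3/20
  lam2 <- make_ct(pos = c(2L, 8L), protected = c(2L, 1L), total = c(10L, 10L),
                  source_kind = "lambda_5mC")
  expect_equal(estimate_nonconversion_5mC(lam2)$rate, 0.15)
})

test_that("degenerate calibration inputs give the boundary rates or errors", {
  lam <- make_ct(pos = c(1L, 5L), protected = 0L, total = c(4L, 6L),
                 source_kind = "lambda_5mC")
  expect_equal(estimate_nonconversion_5mC(lam)$rate, 0)
  puc <- make_ct(pos = 1L, protected = 5L, total = 5L, source_kind = "pUC19_5hmC")
  expect_equal(estimate_protection_rate(puc)$rate, 1)
  puc0 <- make_ct(pos = 1L, protected = 0L, total = 5L, source_kind = "pUC19_5hmC")
  expect_equal(estimate_protection_rate(puc0)$rate, 0)
  # CG-only genomic input has no non-CG sites to estimate from
  cg_only <- make_ct(pos = 1L, protected = 0L, total = 5L)
  expect_error(estimate_nonconversion_C(cg_only), "undefined",
               class = "hydroxymeta_validation_error")
  # source-kind mix-ups are refused
  expect_error(estimate_nonconversion_5mC(cg_only),
               class = "hydroxymeta_validation_error")
  expect_error(estimate_protection_rate(cg_only),
               class = "hydroxymeta_validation_error")
})

test_that("simulated spike-ins recover their configured rates within exact 99% CIs", {
  # spike-in depth sized so every estimator rests on >= 10,000 observations
  sim <- simulate_dataset(small_cfg(seed = 5, coverage = 2,
                                    spikein_coverage = 80))
  truth <- sim$truth$rates
  ests <- list(estimate_nonconversion_5mC(sim$lambda_calls),
               estimate_nonconversion_C(sim$calls),
               estimate_protection_rate(sim$puc19_calls))
  for (i in seq_along(ests)) {
    expect_gte(ests[[i]]$total, 10000)
    ci <- confint(ests[[i]], level = 0.99)
    expect_gte(truth[[i]], ci[1L, "lower"])
    expect_lte(truth[[i]], ci[1L, "upper"])
  }
})

test_that("global %5hmCG is total protected over total coverage at 2-decimal display", {
  lev <- global_5hmCG(ct_with_counts(159774L, 4695778L, "High"))
  expect_equal(sprintf("%.2f", round(lev$pct_5hmCG, 2)), "3.40")
  expect_equal(lev$total_5hmCG, 159774)
  expect_equal(lev$total_CG, 4695778)
  # zero protected reads -> 0.00%
  expect_equal(global_5hmCG(make_ct(1L, 0L, 10L))$pct_5hmCG, 0)
  # non-CG calls are excluded from the global level
  mixed <- call_table(data.frame(chrom = "c", pos = c(1L, 5L), strand = "+",
                                 context = c("CG", "CHH"),
                                 protected = c(1L, 9L), total = c(10L, 9L)))
  expect_equal(global_5hmCG(mixed)$pct_5hmCG, 10)
  expect_error(global_5hmCG(make_ct(1L, 0L, 5L, context = "CHH")),
               class = "hydroxymeta_validation_error")
})

test_that("adding a fully protected call cannot decrease the global level", {
  base <- make_ct(pos = c(1L, 5L), protected = c(1L, 2L), total = c(9L, 11L))
  more <- make_ct(pos = c(1L, 5L, 9L), protected = c(1L, 2L, 4L),
                  total = c(9L, 11L, 4L))
  expect_gte(global_5hmCG(more)$pct_5hmCG, global_5hmCG(base)$pct_5hmCG)
})

test_that("protection-rate scaling reproduces the published raw/scaled pairs", {
  lev <- global_5hmCG(ct_with_counts(159774L, 4695778L))
  s <- scale_pct(lev, 0.5231)
  expect_equal(sprintf("%.2f", round(s$scaled_pct, 2)), "6.50")
  lev2 <- global_5hmCG(ct_with_counts(88910L, 4004237L))
  s2 <- scale_pct(lev2, 0.4847)
  expect_equal(sprintf("%.2f", round(s2$scaled_pct, 2)), "4.58")
  # protection 1 is the identity; 0 is an error; >100% caps with a warning
  expect_equal(scale_pct(lev, 1)$scaled_pct, lev$pct_5hmCG)
  expect_error(scale_pct(lev, 0), class = "hydroxymeta_validation_error")
  high <- global_5hmCG(make_ct(1L, 9L, 10L))
  expect_warning(capped <- scale_pct(high, 0.5), "capping")
  expect_equal(capped$scaled_pct, 100)
})

test_that("coverage in genome equivalents is mean depth per reference cytosine", {
  ct <- make_ct(pos = c(1L, 5L, 9L), protected = 0L, total = c(1L, 1L, 1L))
  expect_equal(estimate_coverage(ct, 3L), 1)
  # half the reference covered at depth 2 averages to 1
  ct2 <- make_ct(pos = c(1L, 5L), protected = 0L, total = c(2L, 2L))
  expect_equal(estimate_coverage(ct2, 4L), 1)
  expect_error(estimate_coverage(ct, 0L), class = "hydroxymeta_validation_error")
  # simulation at a configured depth is recovered
  sim <- simulate_dataset(small_cfg(seed = 9, coverage = 0.4))
  cov <- estimate_coverage(sim$calls, sim$truth$n_reference_cytosines)
  expect_equal(cov, 0.4, tolerance = 0.05)
})
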