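test_that("vectorised panel calling matches the single-position route", {
  sp <- small_panel()
  ecfg <- small_error_cfg()
  ccfg <- caller_config()
  calls <- call_panel(sp$panel, ccfg, ecfg, samples = c("test01", "test02"))
  expect_gt(nrow(calls), 100)
  set.seed(1)
  qc <- c("q_poisson_f", "q_poisson_r", "q_fisher_f", "q_fisher_r",
          "q_empirical_f", "q_empirical_r", "maf")
  for (i in sample.int(nrow(calls), 30)) {
    r <- calls[i]
    s <- call_position(r$sample, r$pos, sp$panel, ccfg, ecfg)
    expect_equal(as.list(r[, ..qc]), as.list(s[, ..qc]), tolerance = 1e-10,
                 info = paste(r$sample, r$pos))
    expect_identical(r$called_poisson, s$called_poisson)
    expect_identical(r$called_empirical, s$called_empirical)
  }
})

test_that("planted mutations are called and error positions are not", {
  sp <- small_panel()
  calls <- call_panel(sp$panel, caller_config(min_minor_freq = 0.04),
                      small_error_cfg(), samples = c("test01", "test02"))
  truth <- sp$truth
  hit <- merge(calls, truth, by = c("sample", "pos"))
  expect_equal(nrow(hit), 2L)
  expect_true(all(hit$called_poisson))
  expect_true(all(hit$called_fisher))
  expect_true(all(hit$minor == c("A", "C", "G", "T")[hit$allele]))
  # no false positives at these depths
  others <- calls[!truth, on = c("sample", "pos")]
  expect_equal(sum(others$called_poisson), 0L)
  expect_equal(sum(others$called_fisher), 0L)
  expect_equal(sum(others$called_empirical, na.rm = TRUE), 0L)
})

test_that("strand rule and frequency threshold gate the call flag", {
  cfg10 <- caller_config()
  expect_true(minorcall:::strand_rule_pass(59, 10, cfg10))
  expect_false(minorcall:::strand_rule_pass(60, 0, cfg10))     # both strands needed
  expect_false(minorcall:::strand_rule_pass(60, NA, cfg10))    # missing strand fails
  cfgsum <- caller_config(strand_rule = "sum", min_quality = 25)
  expect_true(minorcall:::strand_rule_pass(20, 6, cfgsum))
  expect_false(minorcall:::strand_rule_pass(20, 4, cfgsum))
  # a 4.6% minor allele is not reported under the 5% criterion regardless of Q
  sp <- small_panel()
  calls5 <- call_panel(sp$panel, caller_config(min_minor_freq = 0.05),
                       small_error_cfg(), samples = "test01")
  low <- calls5[maf < 0.05]
  expect_equal(sum(low$called_poisson), 0L)
})

test_that("quality caps hold across a simulated panel", {
  sp <- small_panel()
  calls <- call_panel(sp$panel, caller_config(), small_error_cfg(),
                      samples = c("test01", "test02"))
  R <- length(sp$panel$samples) - 1L
  emp_cap <- -10 * log10(1 / (R + 1))
  for (col in c("q_poisson_f", "q_poisson_r", "q_fisher_f", "q_fisher_r")) {
    expect_true(all(calls[[col]] <= 60 + 1e-9, na.rm = TRUE))
    expect_true(all(calls[[col]] >= 0, na.rm = TRUE))
  }
  for (col in c("q_empirical_f", "q_empirical_r"))
    expect_true(all(calls[[col]] <= emp_cap + 1e-9, na.rm = TRUE))
})

test_that("degraded references disable the empirical method only", {
  sp <- small_panel()
  calls <- call_panel(sp$panel, caller_config(),
                      error_model_config(min_reference_samples = 50L),
                      samples = "test01")
  expect_true(all(calls$degraded_reference))
  expect_true(all(is.na(calls$q_empirical_f)))
  expect_true(all(is.na(calls$called_empirical)))
  expect_false(anyNA(calls$q_poisson_f[calls$depth > 0]))
  # single-sample panel: everything degraded, Poisson on the fallback rate
  solo <- pileup_panel(sp$panel$samples["test01"])
  c1 <- call_panel(solo, caller_config(), error_model_config())
  expect_true(all(c1$degraded_reference))
})

test_that("common variants in the panel stay callable through the rate cap", {
  # plant the same variant in most panel members: the pooled "error" rate at
  # that site is high, and without the cap the query's copy would be masked
  cfg <- sim_config(target_length = 600L, n_reads = 3000L, seed = 21L,
                    n_reference_samples = 30L)
  ref <- random_reference(600L, 21L)
  seeds <- minorcall:::sample_seeds(21L, 31L)
  pos <- 300L; allele <- setdiff(1:4, ref[pos])[1]
  pls <- lapply(1:30, function(i)
    sim_sample_pileup(ref, cfg, seeds[i], sprintf("ref%02d", i),
                      llm = list(pos = pos, allele = allele, freq = 0.3)))
  pls[[31]] <- sim_sample_pileup(ref, cfg, seeds[31], "test01",
                                 llm = list(pos = pos, allele = allele,
                                            freq = 0.3))
  panel <- pileup_panel(pls)
  ecfg <- error_model_config(min_reference_samples = 5L)
  on_cap <- call_panel(panel, caller_config(apply_common_cap = TRUE),
                       ecfg, samples = "test01")
  off_cap <- call_panel(panel, caller_config(apply_common_cap = FALSE),
                        ecfg, samples = "test01")
  expect_true(on_cap[pos == 300L]$common_variant_capped)
  expect_true(on_cap[pos == 300L]$called_poisson)
  expect_false(off_cap[pos == 300L]$called_poisson)
})
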