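make_consensus <- function(L, samples, base = 1L) {
  m <- matrix(base, L, length(samples))
  colnames(m) <- samples
  m
}

test_that("contamination verdicts follow the screen rules", {
  L <- 1000L
  cons <- make_consensus(L, c("S", "X", "Y"))
  # X differs from S at 25 positions; S's minor alleles match X at 17 of them
  diffpos <- seq(10L, 250L, by = 10L)
  cons[diffpos, "X"] <- 3L
  calls <- data.table::data.table(sample = "S", pos = diffpos[1:17],
                                  minor = "G", called = TRUE)
  rep <- screen_contamination(calls, cons)
  expect_equal(rep$candidate, "X")
  expect_equal(rep$verdict, "strong")                  # all 17 explained, 68% of diffs
  expect_equal(rep$n_explained, 17L)
  expect_gt(rep$explained_fraction, 0.6)
  # five or fewer verified minor alleles: not screened
  few <- calls[1:4]
  expect_equal(nrow(screen_contamination(few, cons)), 0L)
  # partially explained: 8 verified, only 3 matching X
  part <- data.table::data.table(sample = "S",
                                 pos = c(diffpos[1:3], 500:504),
                                 minor = c(rep("G", 3), rep("C", 5)),
                                 called = TRUE)
  rp <- screen_contamination(part, cons)
  expect_equal(rp$verdict, "partial")
  # no shared minor alleles anywhere: verdict none
  none <- data.table::data.table(sample = "S", pos = 600:607, minor = "T",
                                 called = TRUE)
  rn <- screen_contamination(none, cons)
  expect_equal(rn$verdict, "none")
})

test_that("mixture proportion averages contaminant-allele frequencies", {
  sc <- collapsed_bins(10)
  tal <- data.table::rbindlist(lapply(1:4, function(p)
    data.table::data.table(pos = p, bin = 1L, allele = c(1L, 3L),
                           count = c(90L, 10L))))
  pp <- pileup_from_tally(tal, "S", sc, 6L)
  contam <- rep(3L, 6)
  est <- estimate_mixture_proportion(pp, contam, 1:4)
  expect_equal(est$mean, 0.1)
  expect_equal(est$sd, 0)
  # a missed position counts as zero frequency
  est2 <- estimate_mixture_proportion(pp, contam, c(1:4, 5L))
  expect_equal(est2$n_positions, 4L)                   # position 5 uncovered
  tal3 <- rbind(tal, data.table::data.table(pos = 5L, bin = 1L,
                                            allele = 1L, count = 100L))
  pp3 <- pileup_from_tally(tal3, "S", sc, 6L)
  est3 <- estimate_mixture_proportion(pp3, contam, c(1:4, 5L))
  expect_equal(est3$mean, mean(c(rep(0.1, 4), 0)))
  expect_error(estimate_mixture_proportion(pp, contam, integer(0)), "differing")
})

test_that("mixture proportion is recovered from simulated two-haplotype reads", {
  L <- 2000L
  hapA <- random_reference(L, 41L)
  hapB <- hapA
  dpos <- seq(80L, 2000L, by = 80L)                    # 25 differing positions
  for (p in dpos) hapB[p] <- setdiff(1:4, hapA[p])[1]
  cfg <- sim_config(target_length = L, n_reads = 26000L, seed = 42L)  # ~1,000x
  for (frac in c(0.5, 0.25, 0.1)) {                    # 1:1, 1:3, 1:9 mixtures
    sim <- simulate_mixture(hapA, hapB, frac, cfg, seed = 1000L + frac * 100,
                            sample_id = "mix")
    pp <- sim_reads_to_pileup(sim)
    est <- estimate_mixture_proportion(pp, hapB, dpos)
    # within 3 binomial standard errors of the true fraction
    se <- sqrt(frac * (1 - frac) / (26000 * 75 / L))
    expect_lt(abs(est$mean - frac), 3 * se)
    expect_equal(nrow(sim$truth), 25L)
    expect_true(all(sim$truth$freq == frac))
  }
})

test_that("chimeric-read expectations follow the even-redistribution model", {
  # 10 of 39 other samples carry G, depth 1,000, f = 0.15
  a <- assess_chimera(30, 1000, 10 / 39, f = 0.15)
  expect_equal(a$expected_count, 0.15 * 10 / 39 * 1000, tolerance = 1e-9)
  expect_true(a$explainable)                           # 30 < 38.5 expected
  b <- assess_chimera(200, 1000, 10 / 39, f = 0.15)
  expect_false(b$explainable)                          # far above expectation
  # nothing is explainable without carriers (or with f = 0), except zero counts
  expect_false(assess_chimera(5, 1000, 0)$explainable)
  expect_true(assess_chimera(0, 1000, 0)$explainable)
  expect_false(assess_chimera(5, 1000, 0.3, f = 0)$explainable)
})

test_that("chimera screen annotates calls by library composition", {
  L <- 50L
  cons <- make_consensus(L, c("A1", "A2", "A3", "B1"))
  cons[20L, "A2"] <- 3L                                # one library mate carries G
  calls <- data.table::data.table(sample = "A1", pos = 20L, minor = "G",
                                  minor_count = 8L, depth = 100L)
  libs <- c(A1 = "L1", A2 = "L1", A3 = "L1", B1 = "L2")
  out <- chimera_screen(calls, cons, libs, f = 0.15)
  expect_equal(out$chimera_share, 0.5)                 # 1 of 2 library mates
  expect_equal(out$chimera_expected, 100 * 0.15 * 0.5)
  expect_true(out$chimera_explainable)
  # unassigned samples are skipped with a warning
  calls2 <- data.table::data.table(sample = "Z", pos = 20L, minor = "G",
                                   minor_count = 8L, depth = 100L)
  expect_warning(chimera_screen(calls2, cons, libs), "library")
})

test_that("injected chimeras transfer alleles at the expected rate", {
  L <- 1200L
  refA <- random_reference(L, 51L)
  refB <- refA
  dpos <- seq(100L, 1200L, by = 100L)
  for (p in dpos) refB[p] <- setdiff(1:4, refA[p])[1]
  cfg <- sim_config(target_length = L, n_reads = 8000L, seed = 52L,
                    error_rate = 0)
  simA <- simulate_sample(refA, cfg, 61L, "A")
  simB <- simulate_sample(refB, cfg, 62L, "B")
  sims <- inject_chimeras(list(simA, simB), fraction = 0.15, seed = 63L)
  ppA <- sim_library_pileup(sims, 1L)
  # cross-sample allele frequency at differing sites ~ 0.15
  fr <- vapply(dpos, function(p) {
    cnt <- pileup_counts(ppA, p)
    sum(cnt[refB[p], ]) / sum(cnt)
  }, 0)
  expect_lt(abs(mean(fr) - 0.15), 0.02)
  # fraction 0 is the identity
  sims0 <- inject_chimeras(list(simA, simB), fraction = 0, seed = 64L)
  expect_true(all(sims0[[1]]$reads$template == 1L))
  expect_error(inject_chimeras(list(simA), 0.1), "2 samples")
})
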