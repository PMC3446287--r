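#' Simulation study: false discovery rate and power over a depth x MAF grid
#'
#' Re-creates the validation design: a 16,569-bp target sequenced with 76-bp
#' reads at a uniform 1% error rate, read counts 40k/100k/200k/400k (nominal
#' 200x/500x/1,000x/2,000x), planted low-level mutations at minor-allele
#' frequencies 2-10% and 20%, and a reference panel above the 50-sample
#' gate. Each replicate is one test sample carrying a single mutation at a
#' uniformly random position; replicates are grouped into panels that share
#' a fresh set of error-only reference samples, and every query uses all
#' other panel samples as its reference set. Calls use a minimum per-strand
#' quality of 10 on both strands and the study's 5% minor-allele-frequency
#' reporting criterion.
#'
#' @param seed master seed; all panel seeds derive from it.
#' @param read_counts reads per sample, one entry per depth tier.
#' @param mafs planted minor-allele frequencies.
#' @param replicates replicates (test samples) per (depth, MAF) cell.
#' @param n_reference_samples error-only reference samples per panel.
#' @param replicates_per_panel replicates sharing one reference panel.
#' @param target_length,read_length,error_rate simulation parameters.
#' @param caller_cfg a [caller_config()] (default: the study configuration).
#' @param error_cfg an [error_model_config()].
#' @return list with `cells` (data.table depth_reads, maf, n_planted and
#'   per-method detected counts), `totals` (per-method called / false-call
#'   counts and FDR in percent), and `fdr_percent` (pooled over methods).
#' @export
simulation_study <- function(seed = 1L,
                             read_counts = c(40000L, 100000L, 200000L, 400000L),
                             mafs = c(0.02, 0.03, 0.04, 0.05, 0.06, 0.07,
                                      0.08, 0.09, 0.10, 0.20),
                             replicates = 20L,
                             n_reference_samples = 51L,
                             replicates_per_panel = 10L,
                             target_length = 16569L, read_length = 76L,
                             error_rate = 0.01,
                             caller_cfg = caller_config(min_minor_freq = 0.05),
                             error_cfg = error_model_config()) {
  methods <- caller_cfg$methods
  cells <- CJ(depth_reads = read_counts, maf = mafs)
  for (m in methods) set(cells, j = paste0("detected_", m), value = 0L)
  cells[, n_planted := 0L]
  totals <- data.table(method = methods, called = 0L, false_calls = 0L)
  maxchunks <- replicates  # upper bound on panels per depth
  panel_seeds <- matrix(sample_seeds(seed, length(read_counts) * maxchunks),
                        nrow = length(read_counts))
  for (di in seq_along(read_counts)) {
    # deeper tiers carry more error rows per sample; smaller panels keep the
    # reference aggregates within memory
    rpp <- if (read_counts[di] >= 200000L) min(replicates_per_panel, 5L)
           else replicates_per_panel
    chunks <- split(seq_len(replicates), ceiling(seq_len(replicates) / rpp))
    for (ci in seq_along(chunks)) {
      nrep <- length(chunks[[ci]])
      cfg <- sim_config(target_length = target_length,
                        read_length = read_length,
                        n_reads = read_counts[di], error_rate = error_rate,
                        n_reference_samples = n_reference_samples,
                        seed = panel_seeds[di, ci])
      test_freqs <- rep(mafs, each = nrep)
      sp <- simulate_panel(cfg, test_freqs = test_freqs)
      tests <- sprintf("test%02d", seq_along(test_freqs))
      # reference set = the error-only reference samples, so the effective
      # panel size R is the configured one regardless of how many test
      # replicates share a panel
      refs <- sprintf("ref%02d", seq_len(n_reference_samples))
      calls <- call_panel(sp$panel, caller_cfg, error_cfg, samples = tests,
                          reference_samples = refs)
      truth <- sp$truth
      hit <- merge(calls, truth, by = c("sample", "pos"))
      hit <- hit[minor == ALLELES[allele]]
      for (m in methods) {
        ccol <- paste0("called_", m)
        ncalled <- sum(calls[[ccol]], na.rm = TRUE)
        det <- hit[hit[[ccol]] %in% TRUE, .(sample, freq)]
        nfalse <- ncalled - nrow(det)
        totals[method == m, `:=`(called = called + ncalled,
                                 false_calls = false_calls + nfalse)]
        if (nrow(det)) {
          dc <- det[, .N, by = freq]
          for (r in seq_len(nrow(dc)))
            cells[depth_reads == read_counts[di] & maf == dc$freq[r],
                  (paste0("detected_", m)) :=
                    get(paste0("detected_", m)) + dc$N[r]]
        }
      }
      cells[depth_reads == read_counts[di] & maf %in% mafs,
            n_planted := n_planted + nrep]
      rm(sp, calls, hit, truth)
      gc(FALSE)
    }
  }
  totals[, fdr_percent := fifelse(called > 0, 100 * false_calls / called, 0)]
  pooled <- if (sum(totals$called) > 0)
    100 * sum(totals$false_calls) / sum(totals$called) else 0
  list(cells = cells[], totals = totals[], fdr_percent = pooled)
}

#' Null study: quality scores on an error-only panel
#'
#' Simulates a panel with no planted mutations, calls every sample against
#' the others, and summarises the per-strand quality scores of the minor
#' alleles that sequencing error alone produces.
#'
#' @param seed master seed.
#' @param n_samples panel size.
#' @param n_reads reads per sample (default the nominal 500x tier).
#' @param target_length,read_length,error_rate simulation parameters.
#' @param caller_cfg,error_cfg configurations (defaults as in the study).
#' @return list with `median_poisson`, `median_fisher` (medians over all
#'   per-strand qualities, both strands pooled), `median_pf` (both methods
#'   pooled), `empirical_band` (5th/50th/95th percentiles of empirical
#'   strand qualities), and `n_positions`.
#' @export
null_study <- function(seed = 1L, n_samples = 60L, n_reads = 100000L,
                       target_length = 16569L, read_length = 76L,
                       error_rate = 0.01,
                       caller_cfg = caller_config(min_minor_freq = 0.05),
                       error_cfg = error_model_config()) {
  cfg <- sim_config(target_length = target_length, read_length = read_length,
                    n_reads = n_reads, error_rate = error_rate,
                    n_reference_samples = n_samples, seed = seed)
  sp <- simulate_panel(cfg, test_freqs = numeric(0))
  calls <- call_panel(sp$panel, caller_cfg, error_cfg)
  qp <- c(calls$q_poisson_f, calls$q_poisson_r)
  qf <- c(calls$q_fisher_f, calls$q_fisher_r)
  qe <- c(calls$q_empirical_f, calls$q_empirical_r)
  list(median_poisson = median(qp, na.rm = TRUE),
       median_fisher = median(qf, na.rm = TRUE),
       median_pf = median(c(qp, qf), na.rm = TRUE),
       empirical_band = stats::quantile(qe, c(0.05, 0.5, 0.95), na.rm = TRUE),
       n_positions = nrow(calls),
       calls = calls)
}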