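#' Error-model configuration
#'
#' @param min_reference_samples reference-panel size gate: with this many or
#'   fewer reference individuals the position-specific profile is not used
#'   and a fixed fallback error rate is substituted (default 50).
#' @param fallback_error_rate fixed per-bin, per-allele error rate used when
#'   the reference panel is too small (default 0.01).
#' @param common_variant_cap rate at which a bin-allele error rate is capped
#'   when the panel itself carries the variant (default 0.01).
#' @param pseudocount added once to each aggregate bin-allele error count so
#'   pooled rates are strictly positive (default 0.5).
#' @return list of class `error_model_config`.
#' @export
error_model_config <- function(min_reference_samples = 50L,
                               fallback_error_rate = 0.01,
                               common_variant_cap = 0.01,
                               pseudocount = 0.5) {
  stopifnot(fallback_error_rate >= 0, fallback_error_rate <= 1,
            common_variant_cap >= 0, common_variant_cap <= 1,
            pseudocount >= 0)
  cfg <- list(min_reference_samples = as.integer(min_reference_samples),
              fallback_error_rate = fallback_error_rate,
              common_variant_cap = common_variant_cap,
              pseudocount = pseudocount)
  class(cfg) <- "error_model_config"
  cfg
}

#' Position-specific sequencing-error profile from a reference panel
#'
#' For a target position and a query sample, all other samples whose
#' consensus nucleotide at the position equals the query's consensus form the
#' reference panel. Per bin and alternative allele the panel's error counts
#' are pooled into a rate `lambda = (E + pseudocount) / N`; per-sample error
#' frequencies are retained for the empirical rank method. With
#' `min_reference_samples` or fewer reference individuals the profile is
#' marked degraded and `lambda` is replaced by the fixed fallback rate in
#' every bin (the empirical method refuses degraded profiles).
#'
#' @param ref_pos 1-based target position.
#' @param query_sample sample id of the queried individual.
#' @param panel a [pileup_panel()].
#' @param cfg an [error_model_config()].
#' @return object of class `error_profile`: list with `ref_pos`, `consensus`,
#'   `R` (reference-panel size), `degraded`, `bins` (data.table bin / allele /
#'   E (raw pooled error count) / N (pooled depth) / lambda / capped), `freqs`
#'   (data.table bin / allele / sample / freq, only reference samples with at
#'   least one error base), and `Rb` (per-bin count of reference samples with
#'   coverage).
#' @export
build_error_profile <- function(ref_pos, query_sample, panel,
                                cfg = error_model_config()) {
  stopifnot(inherits(panel, "pileup_panel"))
  q <- panel$samples[[query_sample]]
  if (is.null(q)) stop("unknown sample: ", query_sample)
  B <- panel$scheme$n_bins
  consq <- q$cons[ref_pos]
  refs <- Filter(function(s) !identical(s$sample_id, q$sample_id) &&
                   s$depth[ref_pos] > 0L &&
                   !is.na(s$cons[ref_pos]) && !is.na(consq) &&
                   s$cons[ref_pos] == consq,
                 panel$samples)
  R <- length(refs)
  degraded <- R <= cfg$min_reference_samples
  grid <- CJ(bin = seq_len(B), allele = setdiff(1:4, consq))
  E <- numeric(nrow(grid)); N <- numeric(nrow(grid))
  Rb <- integer(B)
  freq_rows <- list()
  for (s in refs) {
    nbs <- s$nb[ref_pos, ]
    Rb <- Rb + (nbs > 0L)
    N <- N + nbs[grid$bin]
    a <- s$alt[.(ref_pos), on = "pos", nomatch = NULL]
    if (nrow(a)) {
      idx <- match(paste(a$bin, a$allele), paste(grid$bin, grid$allele))
      ok <- !is.na(idx)
      E[idx[ok]] <- E[idx[ok]] + a$count[ok]
      if (any(ok))
        freq_rows[[length(freq_rows) + 1L]] <-
          data.table(bin = a$bin[ok], allele = a$allele[ok],
                     sample = s$sample_id,
                     freq = a$count[ok] / nbs[a$bin[ok]])
    }
  }
  bins <- data.table(bin = grid$bin, allele = grid$allele,
                     E = E, N = N)
  bins[, lambda := if (degraded) cfg$fallback_error_rate else
    ifelse(N > 0, (E + cfg$pseudocount) / N, cfg$fallback_error_rate)]
  bins[, capped := FALSE]
  freqs <- if (length(freq_rows)) rbindlist(freq_rows) else
    data.table(bin = integer(), allele = integer(),
               sample = character(), freq = numeric())
  structure(list(ref_pos = ref_pos, consensus = consq, R = R,
                 degraded = degraded, bins = bins,
                 freqs = if (degraded) NULL else freqs,
                 Rb = Rb),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("error_profile @%d: consensus %s, R = %d%s\n", x$ref_pos,
              ifelse(is.na(x$consensus), "?", ALLELES[x$consensus]), x$R,
              if (x$degraded) " (degraded: fixed fallback rate)" else ""))
  invisible(x)
}

#' Cap error rates at common-variant positions
#'
#' When the reference panel itself segregates for a variant, the pooled
#' "error" rate at that position is inflated. Where a one-sided binomial test
#' of the pooled count against `common_variant_cap` rejects in the upper tail
#' at level `alpha`, the rate is clamped to the cap and the bin-allele is
#' flagged, so genuinely common variants remain detectable in the query.
#'
#' @param profile an [build_error_profile()] result (not degraded).
#' @param cfg an [error_model_config()].
#' @param alpha test level (default 0.05).
#' @return the profile with `lambda` capped and `capped` flags set.
#' @export
cap_common_variant <- function(profile, cfg = error_model_config(),
                               alpha = 0.05) {
  if (profile$degraded) stop("cannot cap a degraded profile")
  p0 <- cfg$common_variant_cap
  b <- profile$bins
  pup <- ifelse(b$N > 0,
                pbinom(pmax(b$E - 1, 0), pmax(b$N, 1), p0, lower.tail = FALSE),
                1)
  hit <- b$E > 0 & pup < alpha & b$lambda > p0
  b[hit, `:=`(lambda = p0, capped = TRUE)]
  profile$bins <- b
  profile
}

#' Rank correlation of per-position error rates between data subsets
#'
#' Because absolute error rates vary between runs and lanes, reproducibility
#' of error hot spots across subsets is measured on ranked rates (Spearman).
#'
#' @param rates_subset1,rates_subset2 equal-length numeric vectors of
#'   per-position (per-strand) error rates.
#' @return list with `rho` and `p.value` (two-sided).
#' @export
error_rank_correlation <- function(rates_subset1, rates_subset2) {
  if (length(rates_subset1) != length(rates_subset2))
    stop("rate vectors must have equal length")
  ct <- suppressWarnings(cor.test(rates_subset1, rates_subset2,
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Export an error profile as a tidy table
#' @param profile an `error_profile`.
#' @return data.table: ref_pos, consensus, bin, allele, E, N, lambda, R, flags.
#' @export
profile_table <- function(profile) {
  out <- copy(profile$bins)
  out[, `:=`(ref_pos = profile$ref_pos,
             consensus = ALLELES[profile$consensus],
             allele = ALLELES[allele],
             R = profile$R, degraded = profile$degraded)]
  setcolorder(out, c("ref_pos", "consensus", "bin", "allele",
                     "E", "N", "lambda", "R", "capped", "degraded"))
  out[]
}
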