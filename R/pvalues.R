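#' Poisson deviation P-value for one read bin
#'
#' Upper-tail probability `P(X >= k)` of observing at least the query's
#' minor-allele count in a bin of depth `n`, with `X ~ Poisson(n * lambda)`
#' under the null that the minor allele is sequencing error at the pooled
#' reference rate `lambda`. Vectorised.
#'
#' @param k observed minor-allele count in the bin.
#' @param n bin depth (quality-passing bases).
#' @param lambda pooled reference error rate for the allele (pseudocounted,
#'   strictly positive).
#' @return P-values in (0, 1]; `k = 0` gives exactly 1.
#' @export
poisson_pvalue <- function(k, n, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive (use a pseudocounted rate)")
  if (any(k > n)) stop("k cannot exceed n")
  ppois(k - 1, n * lambda, lower.tail = FALSE)
}

#' One-sided Fisher exact P-value for one read bin
#'
#' Tests enrichment of the minor allele in the query relative to the pooled
#' reference counts, i.e. the upper hypergeometric tail of the 2x2 table
#' `[k, n-k; E, N-E]` with fixed margins. Equivalent to
#' `fisher.test(..., alternative = "greater")`. Vectorised.
#'
#' @param k,n query minor-allele count and bin depth.
#' @param E,N pooled reference error count and depth (raw integers, no
#'   pseudocount).
#' @return P-values in (0, 1]; `k = 0` gives exactly 1.
#' @export
fisher_pvalue <- function(k, n, E, N) {
  if (any(c(k, n, E, N) < 0)) stop("counts must be non-negative")
  if (any(k > n) || any(E > N)) stop("cell count exceeds its margin")
  phyper(k - 1, m = k + E, n = (n - k) + (N - E), k = n, lower.tail = FALSE)
}

#' Empirical rank P-value for one read bin
#'
#' The rank of the observed minor-allele frequency among the per-reference-
#' sample error frequencies in the same bin:
#' `P = (1 + #\{r : freq_r >= k/n\}) / (R + 1)`. Unlike the Poisson and
#' Fisher methods this measures ranking rather than absolute deviation, so
#' its smallest attainable value is `1/(R+1)`.
#'
#' @param k,n query minor-allele count and bin depth (`n > 0`).
#' @param reference_freqs numeric vector of per-reference-sample error
#'   frequencies in the bin (one entry per reference sample with coverage,
#'   zeros included).
#' @return a single P-value in `[1/(R+1), 1]`.
#' @export
empirical_pvalue <- function(k, n, reference_freqs) {
  if (length(reference_freqs) == 0)
    stop("empirical method unavailable: no reference frequencies (degraded profile)")
  if (n <= 0) stop("empirical method needs a covered bin (n > 0)")
  obs <- k / n
  (1 + sum(reference_freqs >= obs)) / (length(reference_freqs) + 1)
}

#' Combine per-bin P-values into a per-strand bias statistic and quality
#'
#' Each covered bin (depth > 0) contributes a Phred-scaled term
#' `min(-10*log10(max(P, floor)), per_bin_cap)`; the per-bin floor is `1e-6`
#' for the Poisson and Fisher methods (so a single bin contributes at most
#' 60) and `1/(R_b+1)` intrinsically for the empirical method. The default
#' bias statistic is the mean of these terms over covered bins — a strand
#' whose minor allele deviates in only one of `m` covered bins can score at
#' most `60/m` — which bounds the influence of any one bin (e.g. duplicate
#' reads) and fixes the per-strand maximum at 60 for Poisson/Fisher and at
#' `-10*log10(1/(R+1))` for the empirical method. Summation with a per-bin
#' cap is available as `combine = "sum"`.
#'
#' @param bin_tests data.frame/data.table with one row per bin on ONE strand:
#'   columns `n` (bin depth) and `p` (the method's P-value; `NA` allowed for
#'   uncovered bins).
#' @param method `"poisson"`, `"fisher"` or `"empirical"`.
#' @param cfg a [caller_config()].
#' @return list with `B` (bias statistic) and `Q` (Phred-like strand quality,
#'   `NA` if the strand has no covered bin).
#' @export
strand_bias_statistic <- function(bin_tests, method = c("poisson", "fisher", "empirical"),
                                  cfg = caller_config()) {
  method <- match.arg(method)
  bt <- as.data.table(bin_tests)
  bt <- bt[n > 0]
  if (!nrow(bt)) return(list(B = NA_real_, Q = NA_real_))
  p <- bt$p
  if (anyNA(p)) stop("covered bin without a P-value")
  if (method %in% c("poisson", "fisher")) p <- pmax(p, cfg$p_floor)
  q <- pmin(-10 * log10(p), cfg$per_bin_cap)
  if (cfg$combine == "mean") {
    B <- mean(q)
    Q <- min(B, cfg$overall_cap)
  } else {
    B <- sum(q)
    Q <- min(B, cfg$overall_cap)
  }
  list(B = B, Q = Q)
}
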