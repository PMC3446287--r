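#' Contamination-screen configuration
#'
#' @param suspect_threshold samples with more than this many verified minor
#'   alleles are screened (default 5 — a single individual is unlikely to
#'   carry more than five heteroplasmies).
#' @param explain_min minimum number of minor alleles a single candidate must
#'   explain for a partial verdict (default 3).
#' @param diff_fraction for a strong verdict the explained positions must
#'   exceed this fraction of the pairwise consensus differences (default 0.6).
#' @return list of class `contamination_config`.
#' @export
contamination_config <- function(suspect_threshold = 5L, explain_min = 3L,
                                 diff_fraction = 0.6) {
  cfg <- list(suspect_threshold = as.integer(suspect_threshold),
              explain_min = as.integer(explain_min),
              diff_fraction = diff_fraction)
  class(cfg) <- "contamination_config"
  cfg
}

#' Screen called minor alleles for cross-contamination
#'
#' A contaminating sample leaves minor alleles identical to its consensus:
#' for every sample with more than `suspect_threshold` verified (called)
#' minor alleles, every other sample is evaluated as a candidate contaminant.
#' A candidate explains a minor allele when its consensus at that position
#' equals the minor allele. Verdicts: `strong` when ALL verified alleles are
#' explained and they represent more than `diff_fraction` of the pairwise
#' consensus differences; `partial` when at least `explain_min` are
#' explained; otherwise `none`.
#'
#' @param calls a [call_panel()]-style table with at least `sample`, `pos`,
#'   `minor` and a logical `called` column (pick one method's flag, e.g.
#'   `called := called_poisson`).
#' @param consensus L x n_samples consensus matrix from [panel_consensus()]
#'   (integer codes or A/C/G/T characters; columns named by sample).
#' @param cfg a [contamination_config()].
#' @return data.table, one row per screened sample: `sample`, `candidate`,
#'   `n_verified`, `n_explained`, `pair_differences`, `explained_fraction`,
#'   `verdict`.
#' @export
screen_contamination <- function(calls, consensus, cfg = contamination_config()) {
  calls <- as.data.table(calls)
  stopifnot(all(c("sample", "pos", "minor", "called") %in% names(calls)))
  if (is.character(consensus[1])) {
    cmat <- matrix(match(consensus, ALLELES), nrow = nrow(consensus),
                   dimnames = dimnames(consensus))
  } else cmat <- consensus
  ver <- calls[called == TRUE]
  ver[, minor_i := allele_index(minor)]
  ids <- colnames(cmat)
  out <- list()
  for (sid in unique(ver$sample)) {
    v <- ver[sample == sid]
    if (nrow(v) <= cfg$suspect_threshold) next
    best <- NULL
    for (cand in setdiff(ids, sid)) {
      expl <- sum(cmat[v$pos, cand] == v$minor_i, na.rm = TRUE)
      both <- !is.na(cmat[, sid]) & !is.na(cmat[, cand])
      ndiff <- sum(cmat[both, sid] != cmat[both, cand])
      frac <- if (ndiff > 0) expl / ndiff else 0
      verdict <- if (expl == nrow(v) && ndiff > 0 && frac > cfg$diff_fraction)
        "strong" else if (expl >= cfg$explain_min) "partial" else "none"
      row <- data.table(sample = sid, candidate = cand,
                        n_verified = nrow(v), n_explained = expl,
                        pair_differences = ndiff, explained_fraction = frac,
                        verdict = verdict)
      if (is.null(best) ||
          expl > best$n_explained ||
          (expl == best$n_explained && frac > best$explained_fraction))
        best <- row
    }
    out[[sid]] <- best
  }
  if (!length(out))
    return(data.table(sample = character(), candidate = character(),
                      n_verified = integer(), n_explained = integer(),
                      pair_differences = integer(),
                      explained_fraction = numeric(), verdict = character()))
  rbindlist(out)
}

#' Estimate the mixture proportion of a contaminant
#'
#' Averages the query sample's frequency of the contaminant's consensus
#' allele over all positions where the two consensus sequences differ —
#' including positions where the expected minor allele was missed (frequency
#' 0) — giving the mean and standard deviation of the minor-component
#' proportion.
#'
#' @param pileup the query sample's `bin_pileup`.
#' @param contaminant_consensus integer- or character-coded consensus of the
#'   candidate contaminant (length L).
#' @param diff_positions positions where the two consensus sequences differ.
#' @return list with `mean`, `sd`, `n_positions`, and the per-position
#'   `freqs`.
#' @export
estimate_mixture_proportion <- function(pileup, contaminant_consensus,
                                        diff_positions) {
  if (!length(diff_positions))
    stop("no differing positions between the two samples")
  cc <- allele_index(contaminant_consensus)
  freqs <- numeric(0)
  used <- integer(0)
  for (p in diff_positions) {
    dep <- pileup$depth[p]
    if (dep == 0L) next
    a <- cc[p]
    cnt <- if (!is.na(pileup$cons[p]) && pileup$cons[p] == a) {
      dep - sum(pileup$alt[pos == p, count])
    } else {
      sum(pileup$alt[pos == p & allele == a, count])
    }
    freqs <- c(freqs, cnt / dep)
    used <- c(used, p)
  }
  if (!length(freqs)) stop("no covered differing positions")
  list(mean = mean(freqs), sd = if (length(freqs) > 1) sd(freqs) else 0,
       n_positions = length(freqs), freqs = setNames(freqs, used))
}

#' Assess whether a minor allele is explainable by chimeric reads
#'
#' In a multiplexed library a fraction `f` of reads derive evenly from the
#' other samples; the expected chimeric minor-allele frequency is then
#' `f x` (share of other samples whose consensus equals the minor allele).
#' The call is *explainable* when a one-sided exact binomial test does NOT
#' find the observed count significantly above that expectation (and at
#' least one other sample carries the allele).
#'
#' @param observed_count minor-allele read count at the position.
#' @param depth total depth at the position.
#' @param allele_share fraction of the other samples in the library whose
#'   consensus equals the minor allele.
#' @param f expected chimeric read fraction (default 0.15).
#' @param alpha rejection level (default 1e-7).
#' @return list: `expected_freq`, `expected_count`, `p_value` (upper-tail
#'   binomial), `explainable`.
#' @export
assess_chimera <- function(observed_count, depth, allele_share, f = 0.15,
                           alpha = 1e-7) {
  stopifnot(f >= 0, f <= 1, allele_share >= 0, allele_share <= 1,
            observed_count <= depth)
  efreq <- f * allele_share
  ecount <- depth * efreq
  p <- pbinom(observed_count - 1, depth, efreq, lower.tail = FALSE)
  list(expected_freq = efreq, expected_count = ecount, p_value = p,
       explainable = (allele_share > 0 || observed_count == 0) && p >= alpha)
}

#' Chimera screen over a call table
#'
#' @param calls a [call_panel()]-style table (`sample`, `pos`, `minor`,
#'   `minor_count`, `depth`).
#' @param consensus consensus matrix from [panel_consensus()].
#' @param libraries named character vector mapping sample -> library id;
#'   samples without an assignment are skipped with a warning.
#' @param f expected chimeric fraction (default 0.15).
#' @param alpha rejection level (default 1e-7).
#' @return the calls with `chimera_share`, `chimera_expected`, `chimera_p`,
#'   `chimera_explainable` columns appended.
#' @export
chimera_screen <- function(calls, consensus, libraries, f = 0.15,
                           alpha = 1e-7) {
  calls <- as.data.table(copy(calls))
  if (is.character(consensus[1])) {
    cmat <- matrix(match(consensus, ALLELES), nrow = nrow(consensus),
                   dimnames = dimnames(consensus))
  } else cmat <- consensus
  calls[, `:=`(chimera_share = NA_real_, chimera_expected = NA_real_,
               chimera_p = NA_real_, chimera_explainable = NA)]
  miss <- setdiff(unique(calls$sample), names(libraries))
  if (length(miss))
    warning("no library assignment for sample(s): ", paste(miss, collapse = ", "),
            "; skipped")
  for (i in seq_len(nrow(calls))) {
    sid <- calls$sample[i]
    if (!sid %in% names(libraries)) next
    mates <- setdiff(names(libraries)[libraries == libraries[[sid]]], sid)
    mates <- intersect(mates, colnames(cmat))
    if (!length(mates)) next
    a <- allele_index(calls$minor[i])
    share <- mean(cmat[calls$pos[i], mates] == a, na.rm = TRUE)
    res <- assess_chimera(calls$minor_count[i], calls$depth[i], share, f, alpha)
    calls[i, `:=`(chimera_share = share,
                  chimera_expected = res$expected_count,
                  chimera_p = res$p_value,
                  chimera_explainable = res$explainable)]
  }
  calls[]
}
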