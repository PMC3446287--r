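#' Caller configuration
#'
#' @param min_quality minimum per-strand Phred-like quality to call a
#'   low-level mutation (default 10).
#' @param per_bin_cap upper limit on a single bin's Phred contribution
#'   (default 60, i.e. the P-value floor; lower it to curb the influence of
#'   duplicate-read-inflated bins further).
#' @param overall_cap upper limit of the per-strand quality for the Poisson
#'   and Fisher methods (default 60).
#' @param p_floor per-bin P-value floor for Poisson/Fisher (default 1e-6,
#'   consistent with the overall cap of 60).
#' @param strand_rule how `min_quality` is applied: `"both_strands"`
#'   (default; each strand must reach it), `"min_strand"` (equivalent), or
#'   `"sum"` (the two strand qualities are added before thresholding).
#' @param min_minor_freq minimum minor-allele frequency for a call
#'   (default 0; the mtDNA study reported calls at >= 0.05 to guard against
#'   low-level cross-contamination).
#' @param methods subset of `c("poisson", "fisher", "empirical")`.
#' @param combine `"mean"` (default) or `"sum"` of per-bin Phred terms.
#' @param apply_common_cap cap reference error rates that are significantly
#'   above `common_variant_cap` (keeps common variants callable).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_quality = 10, per_bin_cap = 60, overall_cap = 60,
                          p_floor = 1e-6,
                          strand_rule = c("both_strands", "min_strand", "sum"),
                          min_minor_freq = 0,
                          methods = c("poisson", "fisher", "empirical"),
                          combine = c("mean", "sum"),
                          apply_common_cap = TRUE) {
  strand_rule <- match.arg(strand_rule)
  combine <- match.arg(combine)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(min_quality >= 0, per_bin_cap > 0, overall_cap > 0,
            p_floor > 0, min_minor_freq >= 0, min_minor_freq <= 1)
  cfg <- list(min_quality = min_quality, per_bin_cap = per_bin_cap,
              overall_cap = overall_cap, p_floor = p_floor,
              strand_rule = strand_rule, min_minor_freq = min_minor_freq,
              methods = methods, combine = combine,
              apply_common_cap = apply_common_cap)
  class(cfg) <- "caller_config"
  cfg
}

strand_rule_pass <- function(qf, qr, cfg) {
  if (cfg$strand_rule == "sum") {
    !is.na(qf) & !is.na(qr) & (qf + qr) >= cfg$min_quality
  } else {
    !is.na(qf) & !is.na(qr) & qf >= cfg$min_quality & qr >= cfg$min_quality
  }
}

#' Score the minor allele of one sample at one position
#'
#' Builds the reference error profile, computes per-bin deviation P-values
#' for each enabled method against the sample's minor allele, combines them
#' into per-strand qualities, and applies the calling rule.
#'
#' @param query_sample sample id.
#' @param ref_pos 1-based target position.
#' @param panel a [pileup_panel()].
#' @param cfg a [caller_config()].
#' @param error_cfg an [error_model_config()].
#' @return one-row data.table (see [call_panel()] for columns), or an empty
#'   table if the sample has no coverage or no minor allele at the position.
#' @export
call_position <- function(query_sample, ref_pos, panel,
                          cfg = caller_config(),
                          error_cfg = error_model_config()) {
  q <- panel$samples[[query_sample]]
  if (is.null(q)) stop("unknown sample: ", query_sample)
  mm <- minor_alleles(q)
  mm <- mm[pos == ref_pos]
  if (!nrow(mm)) return(empty_calls())
  profile <- build_error_profile(ref_pos, query_sample, panel, error_cfg)
  if (cfg$apply_common_cap && !profile$degraded)
    profile <- cap_common_variant(profile, error_cfg)
  scheme <- panel$scheme
  B <- scheme$n_bins
  minor <- mm$minor
  nvec <- q$nb[ref_pos, ]
  kvec <- integer(B)
  qa <- q$alt[pos == ref_pos & allele == minor]
  kvec[qa$bin] <- as.integer(qa$count)
  pb <- profile$bins[allele == minor][order(bin)]
  lam <- pb$lambda[match(seq_len(B), pb$bin)]
  Eb <- pb$E[match(seq_len(B), pb$bin)]
  Nb <- pb$N[match(seq_len(B), pb$bin)]

  res <- mm[, .(sample = query_sample, pos, depth, major = ALLELES[major],
                minor = ALLELES[minor], minor_count, maf)]
  res[, `:=`(q_poisson_f = NA_real_, q_poisson_r = NA_real_,
             q_fisher_f = NA_real_, q_fisher_r = NA_real_,
             q_empirical_f = NA_real_, q_empirical_r = NA_real_,
             called_poisson = NA, called_fisher = NA, called_empirical = NA,
             degraded_reference = profile$degraded,
             common_variant_capped = any(pb$capped))]
  covered <- nvec > 0
  pvals <- function(method) {
    p <- rep(NA_real_, B)
    if (method == "poisson") {
      p[covered] <- poisson_pvalue(kvec[covered], nvec[covered], lam[covered])
    } else if (method == "fisher") {
      p[covered] <- fisher_pvalue(kvec[covered], nvec[covered],
                                  round(Eb[covered]), round(Nb[covered]))
    } else {
      for (b in which(covered)) {
        if (profile$Rb[b] == 0L) { p[b] <- 1; next }  # no reference coverage
        fr <- numeric(profile$Rb[b])
        hits <- profile$freqs[bin == b & allele == minor, freq]
        if (length(hits)) fr[seq_along(hits)] <- hits
        p[b] <- empirical_pvalue(kvec[b], nvec[b], fr)
      }
    }
    p
  }
  for (method in cfg$methods) {
    if (method == "empirical" && profile$degraded) {
      warning("empirical method unavailable at position ", ref_pos,
              ": degraded reference profile (R = ", profile$R, ")")
      next
    }
    p <- pvals(method)
    fbins <- seq_len(scheme$n_segments)
    rbins <- scheme$n_segments + fbins
    sf <- strand_bias_statistic(data.table(n = nvec[fbins], p = p[fbins]), method, cfg)
    sr <- strand_bias_statistic(data.table(n = nvec[rbins], p = p[rbins]), method, cfg)
    res[[paste0("q_", method, "_f")]] <- sf$Q
    res[[paste0("q_", method, "_r")]] <- sr$Q
    res[[paste0("called_", method)]] <-
      strand_rule_pass(sf$Q, sr$Q, cfg) & mm$maf >= cfg$min_minor_freq
  }
  res[]
}

empty_calls <- function() {
  data.table(sample = character(), pos = integer(), depth = integer(),
             major = character(), minor = character(),
             minor_count = integer(), maf = numeric(),
             q_poisson_f = numeric(), q_poisson_r = numeric(),
             q_fisher_f = numeric(), q_fisher_r = numeric(),
             q_empirical_f = numeric(), q_empirical_r = numeric(),
             called_poisson = logical(), called_fisher = logical(),
             called_empirical = logical(),
             degraded_reference = logical(), common_variant_capped = logical())
}

#' Call low-level mutations across a panel
#'
#' For every queried sample and every position with coverage and a nonzero
#' minor allele, computes per-strand qualities under the enabled methods
#' against the reference error profile estimated from the other samples
#' sharing the consensus nucleotide, and applies the calling rule.
#' Vectorised; numerically identical to looping [call_position()].
#'
#' @param panel a [pileup_panel()].
#' @param cfg a [caller_config()].
#' @param error_cfg an [error_model_config()].
#' @param samples sample ids to query (default: all).
#' @param reference_samples sample ids eligible as references (default: all
#'   samples; the query itself is always excluded from its own reference
#'   set).
#' @return data.table, one row per (sample, position): `sample`, `pos`,
#'   `depth`, `major`, `minor`, `minor_count`, `maf`, per-strand qualities
#'   `q_<method>_{f,r}`, `called_<method>` flags, and annotation flags
#'   `degraded_reference`, `common_variant_capped`.
#' @export
call_panel <- function(panel, cfg = caller_config(),
                       error_cfg = error_model_config(),
                       samples = NULL, reference_samples = NULL) {
  stopifnot(inherits(panel, "pileup_panel"))
  ids <- names(panel$samples)
  if (is.null(samples)) samples <- ids
  if (is.null(reference_samples)) reference_samples <- ids
  stopifnot(all(samples %in% ids), all(reference_samples %in% ids))
  scheme <- panel$scheme
  L <- panel$L; B <- scheme$n_bins; nseg <- scheme$n_segments
  pc <- error_cfg$pseudocount

  agg <- panel_reference_aggregates(panel, reference_samples)
  out <- vector("list", length(samples))
  do_emp <- "empirical" %in% cfg$methods

  for (si in seq_along(samples)) {
    qid <- samples[[si]]
    q <- panel$samples[[qid]]
    mm <- minor_alleles(q)
    if (!nrow(mm)) { out[[si]] <- empty_calls(); next }
    self_ref <- qid %in% reference_samples

    qa <- q$alt[mm[, .(pos, allele = minor)], on = c("pos", "allele"), nomatch = NULL]
    qa[, n := q$nb[cbind(pos, bin)]]
    qa[, g := q$cons[pos]]
    qa[, rid := .I]

    # reference aggregates at each (pos, bin) for the query's consensus group:
    # majority-consensus rows take the pooled totals minus the minority
    # corrections; minority rows take the group's own correction sums
    qa[, maj := g == agg$majority[pos]]
    qa[, Nref := 0]; qa[, Rbref := 0L]
    qa[maj == TRUE, `:=`(Nref = agg$Ntot[cbind(pos, bin)],
                         Rbref = agg$Rball[cbind(pos, bin)])]
    if (nrow(agg$corrN)) {
      qa[agg$corrN, `:=`(Nref = fifelse(maj, Nref - i.n, Nref),
                         Rbref = fifelse(maj, Rbref - i.cov, Rbref)),
         on = c("pos", "bin")]
      qa[agg$corrG, `:=`(Nref = fifelse(maj, Nref, as.numeric(i.n)),
                         Rbref = fifelse(maj, Rbref, i.cov)),
         on = c("g", "pos", "bin")]
    }
    if (self_ref) {
      qa[, Nref := Nref - n]
      qa[, Rbref := Rbref - as.integer(n > 0)]
    }
    qa[, ckey := agg$keyfun(g, pos, bin, allele)]
    qa[agg$Etot, Eref := i.E, on = "ckey"]
    qa[is.na(Eref), Eref := 0]
    if (self_ref) qa[, Eref := Eref - count]
    # sample-level reference count at the position
    posinfo <- mm[, .(pos)]
    posinfo[, g := q$cons[pos]]
    posinfo[, R := agg$Rpos[cbind(pos, g)] - as.integer(self_ref)]
    qa[posinfo, R := i.R, on = "pos"]
    qa[, degraded := R <= error_cfg$min_reference_samples]
    qa[, lambda := fifelse(degraded | Nref <= 0, error_cfg$fallback_error_rate,
                           (Eref + pc) / pmax(Nref, 1))]
    if (cfg$apply_common_cap) {
      cap0 <- error_cfg$common_variant_cap
      chk <- qa[, !degraded & Eref > 0 & Nref > 0 & lambda > cap0]
      if (any(chk)) {
        pup <- pbinom(qa$Eref[chk] - 1, round(qa$Nref[chk]), cap0, lower.tail = FALSE)
        hit <- which(chk)[pup < 0.05]
        qa[hit, lambda := cap0]
        qa[, capped := FALSE]; qa[hit, capped := TRUE]
      } else qa[, capped := FALSE]
    } else qa[, capped := FALSE]

    qa[, p_poisson := poisson_pvalue(count, n, lambda)]
    qa[, p_fisher := fisher_pvalue(count, n, round(Eref), round(Nref))]
    if (do_emp) {
      # reference frequencies >= obs within the cell key: entries up to the
      # key's upper bound minus entries strictly below key*2 + obs (equal
      # rationals give identical doubles, so the equality is exact)
      obs <- qa$count / qa$n
      lt <- findInterval(qa$ckey * 2 + obs, agg$fstream, left.open = TRUE)
      hi <- findInterval(qa$ckey * 2 + 1.5, agg$fstream)
      nge <- hi - lt - as.integer(self_ref)  # own row always qualifies
      qa[, p_empirical := fifelse(degraded, NA_real_, (1 + nge) / (Rbref + 1))]
    }

    # per-strand combination (mean over covered bins; absent rows are k=0
    # bins contributing 0)
    qa[, strand := fifelse(bin > nseg, "R", "F")]
    covF <- as.integer(rowSums(q$nb[, seq_len(nseg), drop = FALSE] > 0))
    covR <- as.integer(rowSums(q$nb[, nseg + seq_len(nseg), drop = FALSE] > 0))
    res <- mm[, .(sample = qid, pos, depth, major = ALLELES[major],
                  minor = ALLELES[minor], minor_count, maf)]
    flags <- qa[, .(degraded = any(degraded), capped = any(capped)), by = pos]
    for (method in cfg$methods) {
      pcol <- paste0("p_", method)
      if (method == "empirical" && !pcol %in% names(qa)) next
      qa[, phred := bin_phred(get(pcol), method, cfg)]
      ss <- qa[, .(sF = sum(phred[strand == "F"]),
                   sR = sum(phred[strand == "R"])), by = pos]
      sc <- res[, .(pos)]
      sc[ss, `:=`(sF = i.sF, sR = i.sR), on = "pos"]
      sc[is.na(sF), sF := 0]; sc[is.na(sR), sR := 0]
      mF <- covF[sc$pos]; mR <- covR[sc$pos]
      if (cfg$combine == "mean") {
        qf <- ifelse(mF > 0, pmin(sc$sF / mF, cfg$overall_cap), NA_real_)
        qr <- ifelse(mR > 0, pmin(sc$sR / mR, cfg$overall_cap), NA_real_)
      } else {
        qf <- ifelse(mF > 0, pmin(sc$sF, cfg$overall_cap), NA_real_)
        qr <- ifelse(mR > 0, pmin(sc$sR, cfg$overall_cap), NA_real_)
      }
      deg <- logical(nrow(res))
      if (method == "empirical") {
        # degraded positions: method refused
        deg <- res$pos %in% qa[degraded == TRUE, unique(pos)]
        qf[deg] <- NA_real_; qr[deg] <- NA_real_
      }
      res[[paste0("q_", method, "_f")]] <- qf
      res[[paste0("q_", method, "_r")]] <- qr
      called <- strand_rule_pass(qf, qr, cfg) & res$maf >= cfg$min_minor_freq
      called[deg] <- NA
      res[[paste0("called_", method)]] <- called
    }
    for (col in setdiff(names(empty_calls()), names(res))) {
      res[[col]] <- if (grepl("^called|^degraded|^common", col)) NA else NA_real_
    }
    res[flags, `:=`(degraded_reference = i.degraded,
                    common_variant_capped = i.capped), on = "pos"]
    setcolorder(res, names(empty_calls()))
    out[[si]] <- res
  }
  rbindlist(out)
}

bin_phred <- function(p, method, cfg) {
  if (method %in% c("poisson", "fisher")) p <- pmax(p, cfg$p_floor)
  pmin(-10 * log10(p), cfg$per_bin_cap)
}

# Panel-wide reference aggregates. Samples almost always share the majority
# consensus, so pooled depth/coverage matrices are accumulated over ALL
# reference samples and a small correction table holds the contributions of
# samples whose consensus at a position differs from the majority:
#  Ntot     L x B pooled depths over all reference samples
#  Rball    L x B counts of reference samples with bin coverage
#  Rpos     L x 4 sample counts with depth > 0 and consensus g
#  majority majority consensus allele per position
#  corr     rows (g, pos, bin, n, cov, sample) for minority-consensus samples
#  Etot     pooled error counts by (g, pos, bin, allele)
#  bigalt   per-sample error rows (g, pos, bin, allele, count, n, freq, sample)
panel_reference_aggregates <- function(panel, reference_samples) {
  L <- panel$L; B <- panel$scheme$n_bins
  S <- length(reference_samples)
  keyfun <- function(g, pos, bin, allele)
    (((g - 1) * as.double(L) + (pos - 1)) * B + (bin - 1)) * 4 + allele
  # stack per-sample depth matrices once (pooled depth and per-bin coverage
  # from single rowSums passes); pooled error counts accumulate into a dense
  # per-cell vector — cell keys are unique within a sample, so vectorised
  # indexed addition is exact — and only the packed key*2+frequency vector
  # is retained per sample for the rank stream
  stack <- matrix(0L, L * B, S)
  Rpos <- matrix(0L, L, 4L)
  Edense <- numeric(4 * as.double(L) * B * 4)
  sv <- vector("list", S)
  for (i in seq_len(S)) {
    s <- panel$samples[[reference_samples[[i]]]]
    stack[, i] <- as.vector(s$nb)
    cov <- which(s$depth > 0L)
    idx <- cbind(cov, s$cons[cov])
    Rpos[idx] <- Rpos[idx] + 1L
    if (nrow(s$alt)) {
      a <- s$alt
      g <- s$cons[a$pos]
      n <- s$nb[cbind(a$pos, a$bin)]
      k <- keyfun(g, a$pos, a$bin, a$allele)
      Edense[k] <- Edense[k] + a$count
      sv[[i]] <- k * 2 + a$count / n
    }
  }
  Ntot <- matrix(rowSums(stack), L, B)
  Rball <- matrix(as.integer(rowSums(stack > 0L)), L, B)
  rm(stack)
  majority <- max.col(Rpos, ties.method = "first")
  corr <- vector("list", length(reference_samples))
  for (i in seq_along(reference_samples)) {
    s <- panel$samples[[reference_samples[[i]]]]
    bad <- which(!is.na(s$cons) & s$cons != majority)
    if (length(bad)) {
      cr <- data.table(pos = rep(bad, B),
                       bin = rep(seq_len(B), each = length(bad)),
                       g = rep(s$cons[bad], B),
                       n = as.vector(s$nb[bad, , drop = FALSE]),
                       sample = s$sample_id)
      corr[[i]] <- cr
    }
  }
  corr <- rbindlist(corr)
  if (!nrow(corr))
    corr <- data.table(pos = integer(), bin = integer(), g = integer(),
                       n = integer(), sample = character())
  corrN <- corr[, .(n = sum(n), cov = sum(n > 0L)), by = .(pos, bin)]
  setkey(corrN, pos, bin)
  corrG <- corr[, .(n = sum(n), cov = sum(n > 0L)), by = .(g, pos, bin)]
  setkey(corrG, g, pos, bin)
  # pooled error counts and the sorted per-sample frequency stream, both on
  # the composite cell key ((g-1)*L*B + (pos-1)*B + bin - 1)*4 + allele;
  # the frequency stream packs key and frequency into key*2 + freq, so rank
  # counts within a key reduce to two findInterval() probes
  nzcell <- which(Edense > 0)
  Etot <- data.table(ckey = as.numeric(nzcell), E = Edense[nzcell])
  setkey(Etot, ckey)
  rm(Edense)
  fstream <- unlist(sv, use.names = FALSE)
  rm(sv)
  fstream <- if (is.null(fstream)) numeric(0) else sort(fstream, method = "radix")
  list(Ntot = Ntot, Rball = Rball, Rpos = Rpos, majority = majority,
       corrN = corrN, corrG = corrG, Etot = Etot, fstream = fstream,
       keyfun = keyfun, L = L, B = B)
}
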