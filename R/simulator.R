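#' Simulation configuration
#'
#' Defaults reproduce the validation framework: a 16,569-bp circular
#' mitochondrial-genome-sized target, 76-bp single-end reads, a
#' uniform 1% per-base error rate, and read counts of 40k/100k/200k/400k for
#' the nominal 200x/500x/1,000x/2,000x coverage tiers.
#'
#' @param target_length target length in bp (default 16,569).
#' @param read_length read length in bp (default 76).
#' @param n_reads reads per sample (default 100,000, the nominal 500x tier).
#' @param error_rate per-base substitution error probability (default 0.01);
#'   the erroneous base is uniform over the three alternatives.
#' @param llm_freq planted minor-allele frequency (reads are drawn from the
#'   mutant haplotype with this probability; default 0.05).
#' @param llm_position `"random"` or a fixed 1-based position.
#' @param n_reference_samples error-only reference samples in a panel
#'   (default 51, above the 50-sample reference gate).
#' @param hotspot_map optional data.frame `pos`, `strand` ("F"/"R"),
#'   `multiplier` of per-position strand-specific error-rate multipliers
#'   shared by every sample (error hot spots recur across individuals).
#' @param mixture optional list `(haplotype = integer vector, fraction)` for
#'   two-haplotype mixture samples.
#' @param chimera_fraction optional fraction of reads re-templated from other
#'   samples in the library.
#' @param circular treat the target as circular (reads wrap around the
#'   origin; default TRUE — both the mitochondrial genome and PhiX174 are
#'   circular). Set FALSE for a linear target; linear reads never cross the
#'   ends, which leaves the outermost read-length of positions covered by a
#'   single shallow read bin per strand.
#' @param segment_length,first_used_position bin-scheme parameters.
#' @param seed master seed; per-sample seeds derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(target_length = 16569L, read_length = 76L,
                       n_reads = 100000L, error_rate = 0.01,
                       llm_freq = 0.05, llm_position = "random",
                       n_reference_samples = 51L, hotspot_map = NULL,
                       mixture = NULL, chimera_fraction = NULL,
                       circular = TRUE,
                       segment_length = 10L, first_used_position = 2L,
                       seed = 1L) {
  stopifnot(target_length > 0, read_length > 0, read_length <= target_length,
            n_reads >= 0, error_rate >= 0, error_rate <= 1,
            llm_freq >= 0, llm_freq <= 1)
  cfg <- list(target_length = as.integer(target_length),
              read_length = as.integer(read_length),
              n_reads = as.integer(n_reads), error_rate = error_rate,
              llm_freq = llm_freq, llm_position = llm_position,
              n_reference_samples = as.integer(n_reference_samples),
              hotspot_map = hotspot_map, mixture = mixture,
              chimera_fraction = chimera_fraction,
              circular = isTRUE(circular),
              segment_length = as.integer(segment_length),
              first_used_position = as.integer(first_used_position),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Random reference haplotype
#' @param L length in bp.
#' @param seed RNG seed.
#' @return integer vector (1..4 coding A,C,G,T).
#' @export
random_reference <- function(L, seed = 1L) {
  set.seed(seed)
  sample.int(4L, L, replace = TRUE)
}

# deterministic per-sample seed stream from a master seed
sample_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one sample's reads (read-level path)
#'
#' Uniform random start positions and strands; on a circular target (the
#' default) reads wrap around the origin, on a linear one starts are confined
#' to `1..L-read_length+1`, so all reads are full length either way. Each
#' base is erroneous independently with `error_rate`, the error base uniform
#' over the three alternatives (in reference orientation). If `llm` is given, each
#' read is independently drawn from the mutant haplotype with probability
#' `llm$freq`.
#'
#' @param ref integer-coded reference haplotype (1..4).
#' @param cfg a [sim_config()].
#' @param seed RNG seed for this sample.
#' @param sample_id sample identifier.
#' @param llm optional list `(pos, allele, freq)` of one planted low-level
#'   mutation (allele integer-coded, must differ from the reference base).
#' @param haplotype_b optional full second haplotype (integer vector) used
#'   with `cfg$mixture$fraction` for mixture samples; overrides `llm`.
#' @return object of class `sim_reads`: list with `reads` (data.table
#'   read_id, start, strand, hap), `errors` (data.table read, read_pos,
#'   alt_idx in 1..3), `ref`, `hap_b`, `truth` (data.table of planted
#'   positions/alleles/frequencies), `cfg`, `sample_id`.
#' @export
simulate_sample <- function(ref, cfg, seed, sample_id = "sample", llm = NULL,
                            haplotype_b = NULL) {
  L <- length(ref); rl <- cfg$read_length
  set.seed(seed)
  n <- cfg$n_reads
  hap_b <- NULL; frac <- 0
  truth <- data.table(sample = character(), pos = integer(),
                      allele = integer(), freq = numeric())
  if (!is.null(haplotype_b)) {
    if (length(haplotype_b) != L) stop("haplotypes differ in length")
    hap_b <- haplotype_b
    frac <- cfg$mixture$fraction
    dif <- which(hap_b != ref)
    truth <- data.table(sample = sample_id, pos = dif, allele = hap_b[dif],
                        freq = frac)
  } else if (!is.null(llm)) {
    if (llm$pos < 1L || llm$pos > L) stop("llm position outside target")
    if (ref[llm$pos] == llm$allele) stop("llm allele equals the reference base")
    hap_b <- ref; hap_b[llm$pos] <- llm$allele
    frac <- llm$freq
    truth <- data.table(sample = sample_id, pos = llm$pos,
                        allele = llm$allele, freq = frac)
  }
  reads <- data.table(
    read_id = sprintf("%s_r%06d", sample_id, seq_len(n)),
    start = sample.int(if (cfg$circular) L else L - rl + 1L, n, replace = TRUE),
    strand = c("F", "R")[rbinom(n, 1L, 0.5) + 1L],
    hap = if (is.null(hap_b)) rep(1L, n) else rbinom(n, 1L, frac) + 1L)
  nerr <- rbinom(1L, n * rl, cfg$error_rate)
  slots <- sort(sample.int(n * rl, nerr))
  errors <- data.table(read = (slots - 1L) %/% rl + 1L,
                       read_pos = (slots - 1L) %% rl + 1L,
                       alt_idx = sample.int(3L, nerr, replace = TRUE))
  structure(list(reads = reads, errors = errors, ref = ref, hap_b = hap_b,
                 truth = truth, cfg = cfg, sample_id = sample_id),
            class = "sim_reads")
}

# reference position of each (read, read_pos) pair; wraps on circular targets
sim_ref_pos <- function(reads, read, read_pos, rl, L = NULL) {
  p <- ifelse(reads$strand[read] == "R",
              reads$start[read] + rl - read_pos,
              reads$start[read] + read_pos - 1L)
  if (!is.null(L)) p <- (p - 1L) %% L + 1L
  p
}

# base (integer) of a read at a reference position, before errors
sim_template_base <- function(sim, read, ref_pos) {
  hap <- sim$reads$hap[read]
  base <- sim$ref[ref_pos]
  if (!is.null(sim$hap_b)) {
    b2 <- sim$hap_b[ref_pos]
    base[hap == 2L] <- b2[hap == 2L]
  }
  base
}

# allele observed after an error: uniform over the three alternatives of the
# template base, encoded by alt_idx in 1..3
apply_error <- function(base, alt_idx) {
  alt <- matrix(c(2L, 3L, 4L,  1L, 3L, 4L,  1L, 2L, 4L,  1L, 2L, 3L),
                nrow = 3L)
  alt[cbind(alt_idx, base)]
}

#' Convert simulated reads to a binned pileup
#'
#' The exact per-base accounting used for testing: every bin-eligible base of
#' every read increments one (strand, segment) bin; errors substitute the
#' template base.
#'
#' @param sim a [simulate_sample()] result.
#' @param scheme a [make_bins()] scheme (defaults to the config's).
#' @return a `bin_pileup`.
#' @export
sim_reads_to_pileup <- function(sim, scheme = NULL) {
  cfg <- sim$cfg; rl <- cfg$read_length; L <- length(sim$ref)
  if (is.null(scheme))
    scheme <- make_bins(rl, cfg$segment_length, cfg$first_used_position)
  n <- nrow(sim$reads)
  # all bases: read x read_pos grid, sparse over errors
  read <- rep(seq_len(n), each = rl)
  read_pos <- rep(seq_len(rl), times = n)
  keep <- read_pos >= scheme$first_used_position
  read <- read[keep]; read_pos <- read_pos[keep]
  refpos <- sim_ref_pos(sim$reads, read, read_pos, rl,
                        if (cfg$circular) L else NULL)
  base <- sim_template_base(sim, read, refpos)
  base <- apply_sim_errors(base, sim$errors, read, read_pos, rl)
  strand <- sim$reads$strand[read]
  bin <- assign_bin(strand, read_pos, scheme)
  tal <- data.table(pos = refpos, bin = bin, allele = base)[
    , .(count = .N), by = .(pos, bin, allele)]
  pileup_from_tally(tal, sim$sample_id, scheme, L)
}

# substitute error bases into the expanded base vector (numeric slot keys)
apply_sim_errors <- function(base, errors, read, read_pos, rl) {
  if (!nrow(errors)) return(base)
  key <- (read - 1) * rl + read_pos
  ekey <- (errors$read - 1) * rl + errors$read_pos
  hit <- match(ekey, key)
  ok <- !is.na(hit)
  base[hit[ok]] <- apply_error(base[hit[ok]], errors$alt_idx[ok])
  base
}

#' Simulate a sample directly at pileup level (fast path)
#'
#' Draws the same joint distribution of per-bin counts as
#' [simulate_sample()] + [sim_reads_to_pileup()] without materialising reads:
#' bin slot sets are disjoint, so per-bin depths follow from the read-start
#' counts and per-bin error counts are independent binomials. Planted
#' low-level mutations are resolved per covered bin (mutant-read counts are
#' binomial within each bin because a read covers a position in exactly one
#' bin). Used for panel-scale simulation.
#'
#' @param ref integer-coded reference haplotype.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @param llm optional planted mutation, as in [simulate_sample()].
#' @return a `bin_pileup`.
#' @export
sim_sample_pileup <- function(ref, cfg, seed, sample_id = "sample", llm = NULL) {
  L <- length(ref); rl <- cfg$read_length
  scheme <- make_bins(rl, cfg$segment_length, cfg$first_used_position)
  B <- scheme$n_bins; nseg <- scheme$n_segments
  set.seed(seed)
  nF <- rbinom(1L, cfg$n_reads, 0.5); nR <- cfg$n_reads - nF
  maxstart <- if (cfg$circular) L else L - rl + 1L
  cF <- tabulate(sample.int(maxstart, nF, replace = TRUE), nbins = L)
  cR <- tabulate(sample.int(maxstart, nR, replace = TRUE), nbins = L)
  nb <- matrix(0L, L, B)
  posv <- seq_len(L)
  if (cfg$circular) {
    # windowed start counts with wraparound via a doubled cumulative sum
    SF2 <- c(0L, cumsum(c(cF, cF))); SR2 <- c(0L, cumsum(c(cR, cR)))
    win <- function(S2, a, b) S2[b + L + 1L] - S2[a + L]
    for (s in seq_len(nseg)) {
      lo <- scheme$segments$start[s]; hi <- scheme$segments$end[s]
      nb[, s] <- win(SF2, posv - hi + 1L, posv - lo + 1L)
      nb[, nseg + s] <- win(SR2, posv - rl + lo, posv - rl + hi)
    }
  } else {
    SF <- c(0L, cumsum(cF)); SR <- c(0L, cumsum(cR))
    for (s in seq_len(nseg)) {
      lo <- scheme$segments$start[s]; hi <- scheme$segments$end[s]
      nb[, s] <- cum_clamp(SF, posv - lo + 1L, L) - cum_clamp(SF, posv - hi, L)
      nb[, nseg + s] <- cum_clamp(SR, posv - rl + hi, L) -
        cum_clamp(SR, posv - rl + lo - 1L, L)
    }
  }
  # per-cell error counts: bin slot sets are disjoint, so the counts are
  # independent Binomial(n_cell, rate) draws; hot-spot cells get their
  # elevated rate
  err <- cfg$error_rate
  nbv <- as.vector(nb)
  hotcells <- integer(0); hotrates <- numeric(0)
  if (!is.null(cfg$hotspot_map) && nrow(cfg$hotspot_map)) {
    hm <- as.data.table(cfg$hotspot_map)
    hotcells <- unlist(lapply(seq_len(nrow(hm)), function(r) {
      bins <- if (hm$strand[r] == "F") seq_len(nseg) else nseg + seq_len(nseg)
      hm$pos[r] + (bins - 1L) * L
    }))
    hotrates <- pmin(err * rep(hm$multiplier, each = nseg), 0.75)
  }
  # one binomial total over the uniform-rate slots, allocated uniformly
  # without replacement (equivalent to per-base Bernoulli errors); hot-spot
  # cells are drawn at their own rates
  nbu <- nbv
  if (length(hotcells)) nbu[hotcells] <- 0L
  ecnt <- integer(L * B)
  if (sum(as.double(nbu)) < .Machine$integer.max) {
    cums <- cumsum(nbu)
    total <- cums[L * B]
    netot <- rbinom(1L, total, err)
    if (netot > 0L) {
      slots <- sample.int(total, netot, useHash = netot < total / 2)
      ecnt <- tabulate(findInterval(slots - 0.5, c(0, cums)), nbins = L * B)
    }
  } else {
    ecnt <- rbinom(L * B, nbu, err)  # very deep data: per-cell draws
  }
  if (length(hotcells))
    ecnt[hotcells] <- rbinom(length(hotcells), nbv[hotcells], hotrates)
  cells <- which(ecnt > 0L)
  alt <- data.table(pos = integer(), bin = integer(), allele = integer(),
                    count = integer())
  if (length(cells)) {
    reps <- ecnt[cells]
    ecell <- rep(cells, reps)
    epos <- (ecell - 1L) %% L + 1L
    eallele <- apply_error(ref[epos], sample.int(3L, length(ecell), replace = TRUE))
    # aggregate (cell, allele) via one tabulate over a combined key
    key <- (ecell - 1L) * 4L + eallele
    tab <- tabulate(key, nbins = as.double(L) * B * 4L)
    nz <- which(tab > 0L)
    zcell <- (nz - 1L) %/% 4L + 1L
    alt <- data.table(pos = (zcell - 1L) %% L + 1L,
                      bin = (zcell - 1L) %/% L + 1L,
                      allele = (nz - 1L) %% 4L + 1L,
                      count = tab[nz])
  }
  cons <- ref
  if (!is.null(llm)) {
    if (llm$pos < 1L || llm$pos > L) stop("llm position outside target")
    if (ref[llm$pos] == llm$allele) stop("llm allele equals the reference base")
    p <- llm$pos
    # redo the cell draws at the planted position, split by haplotype
    alt <- alt[pos != p]
    newrows <- vector("list", B)
    for (b in seq_len(B)) {
      nloc <- nb[p, b]
      if (nloc == 0L) next
      m <- rbinom(1L, nloc, llm$freq)          # mutant-haplotype reads
      rate_b <- cell_rate(err, hotcells, hotrates, p + (b - 1L) * L)
      xA <- rbinom(1L, nloc - m, rate_b)
      xB <- rbinom(1L, m, rate_b)
      cnt <- integer(4L)
      cnt[llm$allele] <- m - xB
      if (xA) {                                 # errors on reference reads
        ea <- apply_error(rep(ref[p], xA), sample.int(3L, xA, replace = TRUE))
        cnt <- cnt + tabulate(ea, 4L)
      }
      if (xB) {                                 # errors on mutant reads
        eb <- apply_error(rep(llm$allele, xB), sample.int(3L, xB, replace = TRUE))
        cnt <- cnt + tabulate(eb, 4L)
      }
      cnt[ref[p]] <- 0L                         # consensus bases not in alt
      sel <- which(cnt > 0L)
      if (length(sel))
        newrows[[b]] <- data.table(pos = p, bin = b, allele = sel,
                                   count = cnt[sel])
    }
    alt <- rbind(alt, rbindlist(newrows))
  }
  # when every position's alternative total is strictly below half its depth
  # the nominal consensus cannot flip or tie, so the checked constructor can
  # be skipped (always true at realistic simulated depths)
  depth <- as.integer(rowSums(nb))
  errtot <- integer(L)
  if (nrow(alt)) {
    rs <- rowsum(as.integer(alt$count), alt$pos)
    errtot[as.integer(rownames(rs))] <- as.integer(rs)
  }
  if (all(2L * errtot < depth | depth == 0L)) {
    cons[depth == 0L] <- NA_integer_
    setkey(alt, pos, bin, allele)
    return(structure(list(sample_id = sample_id, scheme = scheme, L = L,
                          nb = nb, cons = cons, alt = alt, depth = depth,
                          cons_tie = integer(0)),
                     class = "bin_pileup"))
  }
  new_bin_pileup(sample_id, scheme, nb, cons, alt, L)
}

# cumulative count lookup clamped to [0, L]
cum_clamp <- function(S, idx, L) S[pmin(pmax(idx, 0L), L) + 1L]

# per-cell error rate under an optional hot-spot map
cell_rate <- function(err, hotcells, hotrates, cellidx) {
  p <- rep(err, length(cellidx))
  if (length(hotcells)) {
    hit <- match(cellidx, hotcells)
    p[!is.na(hit)] <- hotrates[hit[!is.na(hit)]]
  }
  p
}

#' Simulate a multi-sample panel with truth table
#'
#' Reference samples carry no planted mutation; each test sample carries one
#' low-level mutation at a position drawn uniformly on the target (or fixed
#' via `cfg$llm_position`), at the frequencies in `test_freqs`. A shared
#' `hotspot_map` applies to every sample. Pileup-level simulation is used.
#'
#' @param cfg a [sim_config()].
#' @param test_freqs minor-allele frequencies of the test samples (one test
#'   sample per entry; default `cfg$llm_freq`).
#' @param ref optional integer-coded reference haplotype (default: random
#'   from the master seed).
#' @return list: `panel` (a [pileup_panel()]: reference samples named
#'   `ref01...`, test samples `test01...`), `truth` (data.table sample, pos,
#'   allele, freq), `ref`, `cfg`.
#' @export
simulate_panel <- function(cfg, test_freqs = cfg$llm_freq, ref = NULL) {
  if (cfg$n_reference_samples + length(test_freqs) < 2L)
    stop("a panel needs at least 2 samples")
  if (is.null(ref)) ref <- random_reference(cfg$target_length, cfg$seed)
  nref <- cfg$n_reference_samples
  ntest <- length(test_freqs)
  seeds <- sample_seeds(cfg$seed, nref + 2L * ntest)
  pls <- vector("list", nref + ntest)
  truth <- vector("list", ntest)
  for (i in seq_len(nref)) {
    id <- sprintf("ref%02d", i)
    pls[[i]] <- sim_sample_pileup(ref, cfg, seeds[i], id)
  }
  for (j in seq_len(ntest)) {
    id <- sprintf("test%02d", j)
    set.seed(seeds[nref + j])
    p <- if (identical(cfg$llm_position, "random"))
      sample.int(cfg$target_length, 1L) else as.integer(cfg$llm_position)
    allele <- sample(setdiff(1:4, ref[p]), 1L)
    llm <- list(pos = p, allele = allele, freq = test_freqs[j])
    pls[[nref + j]] <- sim_sample_pileup(ref, cfg, seeds[nref + ntest + j], id,
                                         llm = llm)
    truth[[j]] <- data.table(sample = id, pos = p, allele = allele,
                             freq = test_freqs[j])
  }
  list(panel = pileup_panel(pls), truth = rbindlist(truth), ref = ref,
       cfg = cfg)
}

#' Simulate a two-haplotype mixture sample (read-level)
#'
#' Each read is drawn from haplotype B with probability `fraction`; the truth
#' table lists every position where the haplotypes differ, at expected minor
#' frequency `min(fraction, 1 - fraction)`.
#'
#' @param hapA,hapB integer-coded haplotypes of equal length.
#' @param fraction mixing fraction of haplotype B, in (0, 1).
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @return a `sim_reads` object (see [simulate_sample()]).
#' @export
simulate_mixture <- function(hapA, hapB, fraction, cfg, seed,
                             sample_id = "mix") {
  if (length(hapA) != length(hapB)) stop("haplotypes differ in length")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  cfg$mixture <- list(fraction = fraction)
  simulate_sample(hapA, cfg, seed, sample_id, haplotype_b = hapB)
}

#' Inject chimeric reads into a multiplexed library
#'
#' With probability `fraction`, a read keeps its sample label but its
#' template is redrawn uniformly from the other samples' haplotypes —
#' emulating jumping PCR / index misassignment in a multiplexed library.
#' Error events are untouched (they are independent of the template).
#'
#' @param sims list of `sim_reads` objects (>= 2 samples).
#' @param fraction chimera fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return the list with a `template` column added to each sample's reads
#'   (index into `sims` of the donor sample) and base accounting updated.
#' @export
inject_chimeras <- function(sims, fraction, seed = 1L) {
  if (length(sims) < 2L) stop("chimeras need at least 2 samples in the library")
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  set.seed(seed)
  ns <- length(sims)
  for (i in seq_len(ns)) {
    n <- nrow(sims[[i]]$reads)
    tmpl <- rep(i, n)
    flip <- which(rbinom(n, 1L, fraction) == 1L)
    if (length(flip)) {
      pool <- setdiff(seq_len(ns), i)   # donors drawn evenly from the others
      tmpl[flip] <- pool[sample.int(length(pool), length(flip), replace = TRUE)]
    }
    sims[[i]]$reads[, template := tmpl]
  }
  sims
}

# effective template base of each read in a (possibly chimeric) sim: chimeric
# reads carry the donor sample's primary haplotype
chimera_template_base <- function(sims, i, read, ref_pos) {
  tmpl <- sims[[i]]$reads$template
  base <- sim_template_base(sims[[i]], read, ref_pos)
  if (is.null(tmpl)) return(base)
  tread <- tmpl[read]
  for (j in setdiff(unique(tread), i)) {
    sel <- which(tread == j)
    base[sel] <- sims[[j]]$ref[ref_pos[sel]]
  }
  base
}

#' Pileup of a possibly chimeric read-level sample
#' @param sims list of `sim_reads` (after [inject_chimeras()]).
#' @param i index of the sample to pile up.
#' @param scheme optional bin scheme.
#' @return a `bin_pileup`.
#' @export
sim_library_pileup <- function(sims, i, scheme = NULL) {
  sim <- sims[[i]]
  if (is.null(sim$reads$template)) return(sim_reads_to_pileup(sim, scheme))
  cfg <- sim$cfg; rl <- cfg$read_length; L <- length(sim$ref)
  if (is.null(scheme))
    scheme <- make_bins(rl, cfg$segment_length, cfg$first_used_position)
  n <- nrow(sim$reads)
  read <- rep(seq_len(n), each = rl)
  read_pos <- rep(seq_len(rl), times = n)
  keep <- read_pos >= scheme$first_used_position
  read <- read[keep]; read_pos <- read_pos[keep]
  refpos <- sim_ref_pos(sim$reads, read, read_pos, rl,
                        if (cfg$circular) L else NULL)
  base <- chimera_template_base(sims, i, read, refpos)
  base <- apply_sim_errors(base, sim$errors, read, read_pos, rl)
  strand <- sim$reads$strand[read]
  bin <- assign_bin(strand, read_pos, scheme)
  tal <- data.table(pos = refpos, bin = bin, allele = base)[
    , .(count = .N), by = .(pos, bin, allele)]
  pileup_from_tally(tal, sim$sample_id, scheme, L)
}

#' Write simulated reads as SAM
#'
#' Emits a valid single-reference SAM with FLAG (0/16), POS, 76M CIGAR,
#' MAPQ 60, constant Q40 base qualities (unless `qual_char` overridden), and
#' NM/MD tags computed against the reference.
#'
#' @param sim a `sim_reads` object.
#' @param path output SAM path.
#' @param ref_name reference sequence name (default "target").
#' @param qual_char quality character for all bases (default "I" = Q40).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path, ref_name = "target", qual_char = "I") {
  cfg <- sim$cfg; rl <- cfg$read_length; L <- length(sim$ref)
  n <- nrow(sim$reads)
  if (any(sim$reads$start > L - rl + 1L))
    stop("reads wrapping a circular target cannot be written as plain SAM ",
         "records; simulate with circular = FALSE for SAM output")
  refchar <- ALLELES[sim$ref]
  # per-read template haplotype in reference orientation
  seqs <- character(n)
  hap_b_char <- if (!is.null(sim$hap_b)) ALLELES[sim$hap_b] else NULL
  starts <- sim$reads$start
  for (i in seq_len(n)) {
    idx <- starts[i]:(starts[i] + rl - 1L)
    s <- if (sim$reads$hap[i] == 2L && !is.null(hap_b_char))
      hap_b_char[idx] else refchar[idx]
    seqs[i] <- paste(s, collapse = "")
  }
  # apply errors (reference-orientation substitution at the mapped offset)
  if (nrow(sim$errors)) {
    e <- sim$errors
    offs <- ifelse(sim$reads$strand[e$read] == "R", rl - e$read_pos + 1L,
                   e$read_pos)
    for (z in seq_len(nrow(e))) {
      i <- e$read[z]
      tb <- substr(seqs[i], offs[z], offs[z])
      nb <- ALLELES[apply_error(match(tb, ALLELES), e$alt_idx[z])]
      substr(seqs[i], offs[z], offs[z]) <- nb
    }
  }
  flags <- ifelse(sim$reads$strand == "R", 16L, 0L)
  qual <- strrep(qual_char, rl)
  nm <- integer(n); md <- character(n)
  for (i in seq_len(n)) {
    refseg <- refchar[starts[i]:(starts[i] + rl - 1L)]
    qseg <- strsplit(seqs[i], "")[[1L]]
    mis <- which(qseg != refseg)
    nm[i] <- length(mis)
    md[i] <- md_tag(refseg, mis)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, L))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                 sim$reads$read_id, flags, ref_name, starts, rl, seqs, qual,
                 nm, md)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

md_tag <- function(refseg, mismatch_idx) {
  if (!length(mismatch_idx)) return(as.character(length(refseg)))
  parts <- character(0)
  prev <- 0L
  for (m in mismatch_idx) {
    parts <- c(parts, as.character(m - prev - 1L), refseg[m])
    prev <- m
  }
  paste0(paste(parts, collapse = ""), length(refseg) - prev)
}

#' Write an integer-coded haplotype as FASTA
#' @param seq integer-coded sequence (1..4).
#' @param path output path.
#' @param name sequence name.
#' @export
write_reference_fasta <- function(seq, path, name = "target") {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(paste(ALLELES[seq], collapse = ""), name)),
    path)
  invisible(path)
}
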