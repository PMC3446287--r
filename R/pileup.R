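#' @import data.table
#' @importFrom stats ppois phyper pbinom rbinom median sd cor.test setNames
#' @importFrom utils head tail
NULL

# Alleles are coded 1..4 = A,C,G,T throughout the package internals.
ALLELES <- c("A", "C", "G", "T")

allele_index <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  match(toupper(x), ALLELES)
}

#' Per-sample binned pileup
#'
#' Container for one sample's quality-passing base counts over a shared
#' target, stratified by reference position and (strand, read-segment) bin.
#' The consensus allele at each position is the most frequent allele (ties
#' broken to the lexicographically smallest and flagged); counts of the other
#' alleles are kept sparsely.
#'
#' @param sample_id sample identifier.
#' @param scheme a [make_bins()] scheme.
#' @param tally data.table with columns `pos` (1-based reference position),
#'   `bin` (bin id), `allele` (1..4 or A/C/G/T), `count`.
#' @param target_length length of the reference target.
#' @return object of class `bin_pileup`: list with `sample_id`, `scheme`,
#'   `L`, `nb` (L x n_bins integer matrix of per-bin depths), `cons`
#'   (integer consensus allele per position, NA where uncovered), `alt`
#'   (data.table pos/bin/allele/count of non-consensus bases), `depth`
#'   (per-position total), and `cons_tie` (positions where the consensus was
#'   tied).
#' @export
pileup_from_tally <- function(tally, sample_id, scheme, target_length) {
  stopifnot(inherits(scheme, "bin_scheme"))
  L <- as.integer(target_length)
  B <- scheme$n_bins
  tally <- as.data.table(tally)
  if (nrow(tally)) {
    tally <- tally[, .(count = sum(count)), by = .(pos, bin, allele)]
    tally[, allele := allele_index(allele)]
    if (any(tally$pos < 1L | tally$pos > L)) stop("tally position outside target")
    if (any(tally$bin < 1L | tally$bin > B)) stop("tally bin outside scheme")
  } else {
    tally <- data.table(pos = integer(), bin = integer(),
                        allele = integer(), count = integer())
  }
  nb <- matrix(0L, nrow = L, ncol = B)
  if (nrow(tally)) {
    nbt <- tally[, .(n = sum(count)), by = .(pos, bin)]
    nb[cbind(nbt$pos, nbt$bin)] <- as.integer(nbt$n)
  }
  # consensus per position: most frequent allele over all bins
  cons <- rep(NA_integer_, L)
  tie <- integer(0)
  if (nrow(tally)) {
    tot <- tally[, .(cnt = sum(count)), by = .(pos, allele)]
    setorder(tot, pos, -cnt, allele)
    top <- tot[, .(allele = allele[1L], cnt = cnt[1L],
                   tie = .N > 1L && cnt[2L] == cnt[1L]), by = pos]
    cons[top$pos] <- top$allele
    tie <- top[tie == TRUE, pos]
  }
  alt <- tally[cons[pos] != allele]
  setkey(alt, pos, bin, allele)
  structure(list(sample_id = sample_id, scheme = scheme, L = L,
                 nb = nb, cons = cons, alt = alt,
                 depth = as.integer(rowSums(nb)), cons_tie = tie),
            class = "bin_pileup")
}

# fast constructor used by the simulator: `cons` is the nominal (haplotype)
# consensus and `nb` per-bin totals already include the alt counts; the
# consensus is re-derived through the general constructor whenever an
# alternative allele ties or outweighs the nominal one (rare at any
# realistic depth).
new_bin_pileup <- function(sample_id, scheme, nb, cons, alt, L) {
  depth <- as.integer(rowSums(nb))
  cons[depth == 0L] <- NA_integer_
  rebuild <- FALSE
  if (nrow(alt)) {
    am <- allele_pos_matrix(alt, L)          # 4 x L alt totals
    altsum <- colSums(am)
    amax <- pmax(am[1L, ], am[2L, ], am[3L, ], am[4L, ])
    conscnt <- depth - altsum
    over <- amax > conscnt
    even <- which(amax == conscnt & amax > 0)
    # lexicographic tie goes to the smaller allele index
    tielose <- length(even) > 0 &&
      any(max.col(t(am[, even, drop = FALSE]), ties.method = "first") <
            cons[even])
    rebuild <- any(over) || isTRUE(tielose)
  }
  if (rebuild) {
    # per-cell consensus counts = nb minus alt totals, then retally
    consdt <- data.table(pos = rep(seq_len(L), ncol(nb)),
                         bin = rep(seq_len(ncol(nb)), each = L),
                         count = as.vector(nb))
    consdt <- consdt[count > 0]
    altnb <- alt[, .(a = sum(count)), by = .(pos, bin)]
    consdt[altnb, count := count - a, on = c("pos", "bin")]
    consdt <- consdt[count > 0]
    consdt[, allele := cons[pos]]
    return(pileup_from_tally(rbind(alt, consdt[, .(pos, bin, allele, count)]),
                             sample_id, scheme, L))
  }
  setkey(alt, pos, bin, allele)
  structure(list(sample_id = sample_id, scheme = scheme, L = L,
                 nb = nb, cons = cons, alt = alt, depth = depth,
                 cons_tie = integer(0)),
            class = "bin_pileup")
}

#' @export
print.bin_pileup <- function(x, ...) {
  cat(sprintf("bin_pileup '%s': %d positions, mean depth %.1f, %d non-consensus base(s)\n",
              x$sample_id, sum(x$depth > 0), mean(x$depth), sum(x$alt$count)))
  invisible(x)
}

#' Allele counts at one position of a pileup
#' @param pp a `bin_pileup`.
#' @param pos 1-based reference position.
#' @return 4 x n_bins integer matrix (rows A,C,G,T).
#' @export
pileup_counts <- function(pp, pos) {
  B <- pp$scheme$n_bins
  m <- matrix(0L, nrow = 4L, ncol = B, dimnames = list(ALLELES, NULL))
  if (is.na(pp$cons[pos])) return(m)
  m[pp$cons[pos], ] <- pp$nb[pos, ]
  qpos <- pos  # avoid capture of the alt table's own `pos` column in i
  a <- pp$alt[.(qpos), on = "pos", nomatch = NULL]
  if (nrow(a)) {
    # nb totals include the alt bases: move them off the consensus row
    altbin <- integer(B)
    rs <- rowsum(as.integer(a$count), a$bin)
    altbin[as.integer(rownames(rs))] <- as.integer(rs)
    m[pp$cons[pos], ] <- m[pp$cons[pos], ] - altbin
    m[cbind(a$allele, a$bin)] <- m[cbind(a$allele, a$bin)] + as.integer(a$count)
  }
  m
}

#' Minor-allele summary of a pileup
#'
#' One row per position with nonzero depth and a nonzero minor allele:
#' consensus (major) allele, minor allele (second most frequent, ties to the
#' lexicographically smallest), minor count and frequency.
#' @param pp a `bin_pileup`.
#' @return data.table with columns pos, depth, major, minor, minor_count, maf.
#' @export
minor_alleles <- function(pp) {
  if (!nrow(pp$alt))
    return(data.table(pos = integer(), depth = integer(), major = integer(),
                      minor = integer(), minor_count = integer(), maf = numeric()))
  am <- allele_pos_matrix(pp$alt, pp$L)      # 4 x L alt totals
  hit <- which(colSums(am) > 0)
  sub <- t(am[, hit, drop = FALSE])
  minor <- max.col(sub, ties.method = "first")  # ties -> smallest allele
  top <- data.table(pos = hit,
                    depth = pp$depth[hit],
                    major = pp$cons[hit],
                    minor = minor,
                    minor_count = as.integer(sub[cbind(seq_along(hit), minor)]))
  top[, maf := minor_count / depth]
  top[]
}

# 4 x L matrix of alt-allele totals (summed over bins)
allele_pos_matrix <- function(alt, L) {
  v <- numeric(4L * L)
  rs <- rowsum(as.numeric(alt$count), (alt$pos - 1L) * 4L + alt$allele)
  v[as.integer(rownames(rs))] <- rs
  matrix(v, nrow = 4L)
}

#' Bundle per-sample pileups into a panel
#' @param pileups list of `bin_pileup` objects over the same target & scheme.
#' @return object of class `pileup_panel`.
#' @export
pileup_panel <- function(pileups) {
  stopifnot(length(pileups) >= 1, all(vapply(pileups, inherits, TRUE, "bin_pileup")))
  L <- unique(vapply(pileups, `[[`, 1L, "L"))
  if (length(L) != 1L) stop("pileups cover targets of different lengths")
  ids <- vapply(pileups, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicated sample ids in panel")
  names(pileups) <- ids
  structure(list(samples = pileups, L = L,
                 scheme = pileups[[1L]]$scheme),
            class = "pileup_panel")
}

#' @export
print.pileup_panel <- function(x, ...) {
  cat(sprintf("pileup_panel: %d samples over %d bp\n", length(x$samples), x$L))
  invisible(x)
}

#' Consensus table of a panel
#' @param panel a `pileup_panel`.
#' @return L x n_samples integer matrix of consensus alleles (NA uncovered).
#' @export
panel_consensus <- function(panel) {
  m <- vapply(panel$samples, `[[`, integer(panel$L), "cons")
  colnames(m) <- names(panel$samples)
  m
}
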