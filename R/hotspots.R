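#' Hot/cold-spot configuration
#'
#' @param min_depth minimum pooled per-strand depth to call a hot spot
#'   (default 10,000).
#' @param ratio_threshold hot spots are strand-specific: the error rate must
#'   be at least this many times higher on one strand than the other
#'   (default 10).
#' @param cold_ratio cold spots require the rate on one strand below this
#'   fraction of the other strand's (default 0.5).
#' @param tail_factor the Poisson tail probability must be below
#'   `1 / (target_length * tail_factor)` (default 1e6), a familywise-safe
#'   threshold for extreme outliers.
#' @return list of class `hotspot_config`.
#' @export
hotspot_config <- function(min_depth = 10000L, ratio_threshold = 10,
                           cold_ratio = 0.5, tail_factor = 1e6) {
  stopifnot(min_depth > 0, ratio_threshold > 0, cold_ratio > 0, tail_factor > 0)
  cfg <- list(min_depth = as.integer(min_depth),
              ratio_threshold = ratio_threshold,
              cold_ratio = cold_ratio, tail_factor = tail_factor)
  class(cfg) <- "hotspot_config"
  cfg
}

#' Classify one position as error hot spot / cold spot per strand
#'
#' A strand is *hot* when its pooled depth reaches `min_depth`, the upper
#' Poisson tail of its error count under the panel-average rate falls below
#' `1/(L * tail_factor)`, and its error rate is at least `ratio_threshold`
#' times the other strand's (strand-specificity guards against common
#' variants). It is *cold* when its rate is below `cold_ratio` times the
#' other strand's and the lower Poisson tail falls below the same threshold.
#'
#' @param strand_counts list/data.frame with `errors_f`, `depth_f`,
#'   `errors_r`, `depth_r` (pooled non-consensus counts and depths).
#' @param mean_rate panel-average error rate (all positions and reads).
#' @param L target length.
#' @param cfg a [hotspot_config()].
#' @return data.table with one row per strand: `strand`, `depth`, `errors`,
#'   `rate`, `other_rate`, `p_upper`, `p_lower`, `class`.
#' @export
classify_position <- function(strand_counts, mean_rate, L,
                              cfg = hotspot_config()) {
  stopifnot(L > 0)
  sc <- as.list(strand_counts)
  thr <- 1 / (L * cfg$tail_factor)
  one <- function(err, dep, oerr, odep, strand) {
    rate <- if (dep > 0) err / dep else NA_real_
    orate <- if (odep > 0) oerr / odep else NA_real_
    mu <- mean_rate * dep
    pu <- if (dep > 0) ppois(err - 1, mu, lower.tail = FALSE) else NA_real_
    pl <- if (dep > 0) ppois(err, mu) else NA_real_
    cls <- "normal"
    if (dep > 0) {
      ratio_hot <- if (is.na(orate)) rate > 0 else
        (orate == 0 & rate > 0) | (orate > 0 & rate >= cfg$ratio_threshold * orate)
      ratio_cold <- !is.na(orate) && orate > 0 && rate < cfg$cold_ratio * orate
      if (dep >= cfg$min_depth && pu < thr && isTRUE(ratio_hot)) cls <- "hot"
      else if (isTRUE(ratio_cold) && pl < thr) cls <- "cold"
    }
    data.table(strand = strand, depth = dep, errors = err, rate = rate,
               other_rate = orate, p_upper = pu, p_lower = pl, class = cls)
  }
  rbind(one(sc$errors_f, sc$depth_f, sc$errors_r, sc$depth_r, "F"),
        one(sc$errors_r, sc$depth_r, sc$errors_f, sc$depth_f, "R"))
}

#' Scan a panel for sequencing-error hot and cold spots
#'
#' Pools non-consensus counts and depths per position and strand over all
#' samples; the panel-average error rate comes from all positions and reads
#' pooled. Each position x strand is then classified with
#' [classify_position()].
#'
#' @param panel a [pileup_panel()].
#' @param cfg a [hotspot_config()].
#' @return data.table, one row per position x strand, columns as in
#'   [classify_position()] plus `pos`.
#' @export
scan_panel <- function(panel, cfg = hotspot_config()) {
  stopifnot(inherits(panel, "pileup_panel"))
  L <- panel$L; nseg <- panel$scheme$n_segments
  depF <- numeric(L); depR <- numeric(L)
  errF <- numeric(L); errR <- numeric(L)
  for (s in panel$samples) {
    depF <- depF + rowSums(s$nb[, seq_len(nseg), drop = FALSE])
    depR <- depR + rowSums(s$nb[, nseg + seq_len(nseg), drop = FALSE])
    if (nrow(s$alt)) {
      e <- s$alt[, .(cnt = sum(count)), by = .(pos, fwd = bin <= nseg)]
      ef <- e[fwd == TRUE]; er <- e[fwd == FALSE]
      errF[ef$pos] <- errF[ef$pos] + ef$cnt
      errR[er$pos] <- errR[er$pos] + er$cnt
    }
  }
  tot_dep <- sum(depF) + sum(depR)
  mean_rate <- if (tot_dep > 0) (sum(errF) + sum(errR)) / tot_dep else 0
  keep <- which(depF + depR > 0)
  out <- vector("list", length(keep))
  for (z in seq_along(keep)) {
    p <- keep[z]
    r <- classify_position(list(errors_f = errF[p], depth_f = depF[p],
                                errors_r = errR[p], depth_r = depR[p]),
                           mean_rate, L, cfg)
    r[, pos := p]
    out[[z]] <- r
  }
  res <- rbindlist(out)
  setcolorder(res, c("pos", "strand"))
  res[, mean_rate := mean_rate]
  res[]
}
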