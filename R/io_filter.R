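#' Read/base quality-filter configuration
#'
#' Mirrors the quality-control cascade applied before pileup construction:
#' whole reads are dropped when they carry too many low-quality bases, map
#' poorly, or disagree too often with the reference; individual bases below
#' the base-quality floor are then excluded from counting.
#'
#' @param max_low_qual_bases maximum number of bases at or below
#'   `low_qual_threshold` tolerated per read (default 5; use 2 for 36-bp
#'   reads).
#' @param low_qual_threshold Phred score defining a low-quality base
#'   (default 15).
#' @param min_map_quality minimum mapping quality (default 20).
#' @param max_mismatches maximum mismatches against the reference (default 2).
#' @param min_base_quality minimum base quality for a base to be counted
#'   (default 20).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_low_qual_bases = 5L, low_qual_threshold = 15L,
                          min_map_quality = 20L, max_mismatches = 2L,
                          min_base_quality = 20L) {
  cfg <- list(max_low_qual_bases = as.integer(max_low_qual_bases),
              low_qual_threshold = as.integer(low_qual_threshold),
              min_map_quality = as.integer(min_map_quality),
              max_mismatches = as.integer(max_mismatches),
              min_base_quality = as.integer(min_base_quality))
  if (any(unlist(cfg) < 0L)) stop("filter thresholds must be non-negative")
  class(cfg) <- "filter_config"
  cfg
}

#' Read aligned reads from a SAM/BAM file
#'
#' Yields one record per primary alignment (unmapped, secondary and
#' supplementary alignments are skipped). Mismatch counts are taken from the
#' NM tag when present, otherwise recomputed against `reference`.
#'
#' @param path SAM or BAM file.
#' @param sample_id sample identifier attached to every read.
#' @param reference optional reference sequence (character string or
#'   `Biostrings::DNAString`) used to recompute mismatches when NM is absent.
#' @return data.table of class `aligned_reads`, one row per read: `read_id`,
#'   `sample_id`, `strand` ("F"/"R"), `ref_start`, `map_quality`,
#'   `mismatches`, `cigar`, `seq`, `qual` (Phred+33 string).
#' @export
read_sam <- function(path, sample_id, reference = NULL) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags, tag = "NM",
    what = c("qname", "flag", "strand", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = par)[[1L]]
  n <- length(res$pos)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  reads <- data.table(
    read_id = if (n) res$qname else character(),
    sample_id = rep(sample_id, n),
    strand = as.character(ifelse(as.character(res$strand) == "-", "R", "F")),
    ref_start = as.integer(res$pos),
    map_quality = as.integer(res$mapq),
    mismatches = as.integer(nm),
    cigar = as.character(res$cigar),
    seq = as.character(res$seq),
    qual = as.character(res$qual))
  if (anyNA(reads$mismatches)) {
    if (is.null(reference))
      stop("mismatch count (NM tag) missing for read(s) ",
           paste(head(reads$read_id[is.na(reads$mismatches)], 3L), collapse = ", "),
           " and no reference supplied to recompute it")
    idx <- which(is.na(reads$mismatches))
    refchar <- as.character(reference)
    for (i in idx) {
      b <- expand_bases(reads[i])
      refb <- substring(refchar, b$ref_pos, b$ref_pos)
      reads$mismatches[i] <- sum(b$base != refb)
    }
  }
  setattr(reads, "class", c("aligned_reads", class(reads)))
  reads[]
}

#' Apply read-level quality filters
#'
#' Retains reads whose number of bases at or below `low_qual_threshold` does
#' not exceed `max_low_qual_bases`, whose mapping quality is at least
#' `min_map_quality`, and whose mismatch count does not exceed
#' `max_mismatches`. Order is preserved and the operation is idempotent.
#'
#' @param reads an `aligned_reads` table from [read_sam()].
#' @param cfg a [filter_config()].
#' @return filtered `aligned_reads`; counts of reads removed at each stage
#'   are attached as attribute `filter_stats`.
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  lowq <- count_low_quality(reads$qual, cfg$low_qual_threshold)
  keep_lq <- lowq <= cfg$max_low_qual_bases
  keep_mq <- reads$map_quality >= cfg$min_map_quality
  keep_nm <- reads$mismatches <= cfg$max_mismatches
  keep <- keep_lq & keep_mq & keep_nm
  out <- reads[keep]
  setattr(out, "class", class(reads))
  setattr(out, "filter_stats",
          c(input = nrow(reads),
            low_quality = sum(!keep_lq),
            map_quality = sum(keep_lq & !keep_mq),
            mismatches = sum(keep_lq & keep_mq & !keep_nm),
            retained = nrow(out)))
  out
}

count_low_quality <- function(qual, threshold) {
  vapply(qual, function(q) sum(utf8ToInt(q) - 33L <= threshold), 0L,
         USE.NAMES = FALSE)
}

# Expand reads to one row per aligned base: ref_pos, read_pos (sequencing
# order), base, base_quality. Soft-clipped bases and insertions are excluded
# (they do not align to the reference); deletions consume reference only.
# read_pos counts within the full sequenced read (soft clips included) and is
# reversed for reverse-strand reads.
expand_bases <- function(reads) {
  if (!nrow(reads))
    return(data.table(read = integer(), ref_pos = integer(),
                      read_pos = integer(), base = character(),
                      base_quality = integer(), strand = character()))
  cig <- reads$cigar
  qry <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = c("M", "=", "X"))
  refr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, ops = c("M", "=", "X"))
  qlen <- nchar(reads$seq)  # full sequenced length incl. soft clips
  qs <- unlist(IRanges_starts(qry)); qw <- unlist(IRanges_widths(qry))
  rs <- unlist(IRanges_starts(refr))
  nblocks <- lengths(IRanges_starts(qry))
  readidx <- rep(seq_len(nrow(reads)), nblocks)
  # expand blocks to bases
  bw <- qw
  baseread <- rep(readidx, bw)
  off <- sequence(bw) - 1L
  seqpos <- rep(qs, bw) + off
  refpos <- rep(rs, bw) + off + reads$ref_start[baseread] - 1L
  strand <- reads$strand[baseread]
  readpos <- ifelse(strand == "R", qlen[baseread] - seqpos + 1L, seqpos)
  base <- substring(reads$seq[baseread], seqpos, seqpos)
  basequal <- qual_at(reads$qual, baseread, seqpos)
  data.table(read = baseread, ref_pos = as.integer(refpos),
             read_pos = as.integer(readpos), base = base,
             base_quality = basequal, strand = strand)
}

IRanges_starts <- function(x) IRanges::start(x)
IRanges_widths <- function(x) IRanges::width(x)

qual_at <- function(qual, readidx, seqpos) {
  # Phred score of base seqpos in each read's quality string
  ints <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  vapply(seq_along(readidx), function(i) ints[[readidx[i]]][seqpos[i]], 0L)
}

#' Build a binned pileup from filtered reads
#'
#' Each base with quality at least `min_base_quality`, a called nucleotide
#' (not N), and a read position covered by the bin scheme increments exactly
#' one (strand, segment) bin count at its reference position.
#'
#' @param reads filtered `aligned_reads`.
#' @param scheme a [make_bins()] scheme.
#' @param cfg a [filter_config()] (only `min_base_quality` is used here).
#' @param target_length reference length.
#' @param sample_id sample identifier (defaults to the reads' sample).
#' @return a `bin_pileup`.
#' @export
build_pileup <- function(reads, scheme, cfg = filter_config(), target_length,
                         sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(reads)) reads$sample_id[1L] else "sample"
  b <- expand_bases(reads)
  b <- b[base_quality >= cfg$min_base_quality & base %in% ALLELES &
           read_pos >= scheme$first_used_position &
           read_pos <= scheme$read_length]
  if (nrow(b)) {
    b[, bin := assign_bin(strand, read_pos, scheme)]
    tal <- b[, .(count = .N), by = .(pos = ref_pos, bin, allele = base)]
  } else tal <- data.table(pos = integer(), bin = integer(),
                           allele = integer(), count = integer())
  pileup_from_tally(tal, sample_id, scheme, target_length)
}

#' Read a samtools text pileup file
#'
#' Accepts the classic `samtools mpileup` text dialect (chrom, pos, ref,
#' depth, bases, quals). Strand is taken from the case/orientation marks of
#' the base column. Per-base read positions are not present in this format,
#' so all bases collapse into a single segment per strand (a warning is
#' emitted) and indels are skipped.
#'
#' @param path pileup file.
#' @param sample_id sample identifier.
#' @param target_length reference length (defaults to the maximum position).
#' @param cfg a [filter_config()]; bases below `min_base_quality` are dropped.
#' @return a `bin_pileup` built on a [collapsed_bins()] scheme.
#' @export
read_pileup_file <- function(path, sample_id, target_length = NULL,
                             cfg = filter_config()) {
  if (!file.exists(path)) stop("cannot read pileup file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  scheme <- collapsed_bins()
  warning("text pileup input carries no read positions; ",
          "bases collapse into a single segment per strand")
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) {
      if (length(f) >= 4L && f[4L] == "0") next  # zero-depth line
      stop(sprintf("malformed pileup line %d: expected >=6 fields", i))
    }
    linepos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(linepos)) stop(sprintf("malformed pileup line %d: bad position", i))
    parsed <- tryCatch(
      parse_pileup_bases(f[5L], f[6L], toupper(f[3L])),
      error = function(e) stop(sprintf("malformed pileup line %d: %s", i,
                                       conditionMessage(e))))
    if (!nrow(parsed)) next
    parsed <- parsed[qual >= cfg$min_base_quality & base %in% ALLELES]
    if (!nrow(parsed)) next
    parsed[, pos := linepos]
    rows[[i]] <- parsed
  }
  all <- rbindlist(rows)
  if (is.null(target_length))
    target_length <- if (nrow(all)) max(all$pos) else 1L
  if (!nrow(all))
    return(pileup_from_tally(data.table(pos = integer(), bin = integer(),
                                        allele = integer(), count = integer()),
                             sample_id, scheme, target_length))
  all[, bin := ifelse(strand == "R", 2L, 1L)]
  tal <- all[, .(count = .N), by = .(pos, bin, allele = base)]
  pileup_from_tally(tal, sample_id, scheme, target_length)
}

# Parse one pileup base string together with its quality string.
# Returns data.table(base, strand, qual) for counted bases; indels, deletion
# placeholders (*), reference skips (<,>) and read start/end marks are handled
# per the dialect.
parse_pileup_bases <- function(bases, quals, refbase) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  qv <- utf8ToInt(quals) - 33L
  out_base <- character(0); out_strand <- character(0); out_qual <- integer(0)
  i <- 1L; qi <- 1L
  nq <- length(qv)
  while (i <= length(ch)) {
    c <- ch[i]
    if (c == "^") { i <- i + 2L; next }          # start mark + mapq char
    if (c == "$") { i <- i + 1L; next }          # end mark
    if (c %in% c("+", "-")) {                    # indel: skip length + seq
      j <- i + 1L
      num <- ""
      while (j <= length(ch) && grepl("[0-9]", ch[j])) { num <- paste0(num, ch[j]); j <- j + 1L }
      if (num == "") stop("indel mark without length")
      i <- j + as.integer(num)
      next
    }
    # every remaining symbol consumes one quality char
    if (qi > nq) stop("base/quality length mismatch")
    q <- qv[qi]; qi <- qi + 1L
    if (c == ".") { out_base <- c(out_base, refbase); out_strand <- c(out_strand, "F") }
    else if (c == ",") { out_base <- c(out_base, refbase); out_strand <- c(out_strand, "R") }
    else if (c %in% c("A", "C", "G", "T", "N")) { out_base <- c(out_base, c); out_strand <- c(out_strand, "F") }
    else if (c %in% c("a", "c", "g", "t", "n")) { out_base <- c(out_base, toupper(c)); out_strand <- c(out_strand, "R") }
    else if (c %in% c("*", ">", "<")) { i <- i + 1L; next }  # no base counted
    else stop("unexpected pileup symbol '", c, "'")
    out_qual <- c(out_qual, q)
    i <- i + 1L
  }
  data.table(base = out_base, strand = out_strand, qual = out_qual)
}

#' Read a reference FASTA
#' @param path FASTA file (single sequence used).
#' @return list: `seq` (integer-coded 1..4 vector, 0 for ambiguity codes),
#'   `char` (character string), `length`.
#' @export
read_reference <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) < 1L) stop("no sequence in ", path)
  ch <- as.character(s[[1L]])
  v <- match(strsplit(ch, "")[[1L]], ALLELES)
  v[is.na(v)] <- 0L
  list(seq = v, char = ch, length = length(v))
}
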