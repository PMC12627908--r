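# Divergence-tolerant read mapping by exact k-mer seeding and ungapped
# extension, and distillation of placements into conserved-region BED sets.
# This stands in for the mapping + BAM->BED + merge + strip stages of UCE
# discovery: reads are placed wherever their full-length mismatch fraction is
# at most `max_divergence`; ties at distinct positions are flagged ambiguous
# and excluded from conservation evidence.

#' Map reads to a base genome tolerating divergence
#'
#' Each mate is mapped independently. Placement is by exact k-mer seeding
#' (non-overlapping seeds every `seed_kmer` bases along the read, both
#' strands) followed by ungapped extension to full read length; a placement is
#' reported only where the mismatch fraction over the whole read is at most
#' `max_divergence`. Only minimum-mismatch placements are kept; if two or more
#' placements tie at distinct positions the read is reported with
#' `unique = FALSE` and contributes nothing downstream. Positions where either
#' sequence is ambiguous (`N`) or soft-masked case differs are compared
#' case-insensitively; ambiguous bases always count as mismatches.
#'
#' @param pairs a `read_pairs` data frame from [simulate_read_pairs()].
#' @param base the base [genome_assembly()].
#' @param max_divergence maximum mismatch fraction (default 0.05).
#' @param seed_kmer seed length (default 20); must not exceed read length.
#' @param index optional precomputed [kmer_index] of `base` (performance).
#' @return data frame of class `read_placements` with columns `read_id`,
#'   `scaffold`, `start`, `end`, `strand`, `mismatches`, `unique`, plus a
#'   `counters` attribute (reads, placed, ambiguous, unmapped).
#' @export
map_reads <- function(pairs, base, max_divergence = 0.05, seed_kmer = 20L,
                      index = NULL) {
  if (max_divergence <= 0 || max_divergence >= 0.5)
    parameter_error("max_divergence must be in (0, 0.5)")
  w <- attr(pairs, "read_len")
  if (is.null(w) || is.na(w)) w <- unique(nchar(pairs$mate1))
  if (length(w) != 1L)
    parameter_error("reads must all have one length")
  w <- as.integer(w)
  if (seed_kmer > w) parameter_error("seed_kmer must not exceed read length")

  reads <- c(rbind(pairs$mate1, pairs$mate2))
  read_ids <- c(rbind(paste0(pairs$pair_id, "/1"),
                      paste0(pairs$pair_id, "/2")))
  empty <- structure(
    data.frame(read_id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character(),
               mismatches = integer(), unique = logical(),
               stringsAsFactors = FALSE),
    counters = c(reads = length(reads), placed = 0L, ambiguous = 0L,
                 unmapped = length(reads)),
    class = c("read_placements", "data.frame"))
  if (length(reads) == 0L) return(empty)

  if (is.null(index)) index <- kmer_index(base, seed_kmer)
  k <- index$k
  scaf_up <- toupper(genome_scaffolds(base))
  scaf_len <- nchar(scaf_up)

  fwd <- toupper(reads)
  rev <- revcomp(fwd)
  offs <- unique(c(seq.int(0L, w - k, by = max(1L, as.integer(ceiling(k / 2)))),
                   w - k))
  n_reads <- length(reads)

  gather <- function(q, strand) {
    codes <- kmer_codes(paste(q, collapse = ""), k)
    gidx <- rep((seq_len(n_reads) - 1L) * w, each = length(offs)) +
      rep(offs, times = n_reads) + 1L
    hits <- kmer_lookup(index, codes[gidx])
    if (nrow(hits) == 0L)
      return(data.frame(read = integer(), scaf = integer(),
                        gstart = integer(), strand = character()))
    read <- (hits$query - 1L) %/% length(offs) + 1L
    off <- offs[(hits$query - 1L) %% length(offs) + 1L]
    gstart <- hits$pos - off
    ok <- gstart >= 0L & gstart + w <= scaf_len[hits$scaf]
    data.frame(read = read[ok], scaf = hits$scaf[ok], gstart = gstart[ok],
               strand = if (any(ok)) strand else character(),
               stringsAsFactors = FALSE)
  }
  cand <- rbind(gather(fwd, "+"), gather(rev, "-"))
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[!duplicated(cand[c("read", "scaf", "gstart")]), , drop = FALSE]

  qstr <- ifelse(cand$strand == "+", fwd[cand$read], rev[cand$read])
  win <- substring(scaf_up[cand$scaf], cand$gstart + 1L, cand$gstart + w)
  mm <- hamming_batch(qstr, win, w)
  keep <- mm <= max_divergence * w
  cand <- cand[keep, , drop = FALSE]
  mm <- mm[keep]
  if (nrow(cand) == 0L) return(empty)

  best <- ave(mm, cand$read, FUN = min)
  sel <- mm == best
  cand <- cand[sel, , drop = FALSE]
  mm <- mm[sel]
  nplace <- ave(rep(1L, nrow(cand)), cand$read, FUN = sum)
  uniq <- nplace == 1L

  out <- data.frame(
    read_id = read_ids[cand$read],
    scaffold = names(scaf_up)[cand$scaf],
    start = cand$gstart,
    end = cand$gstart + w,
    strand = cand$strand,
    mismatches = mm,
    unique = uniq,
    stringsAsFactors = FALSE
  )
  placed_reads <- unique(cand$read[uniq])
  ambig_reads <- unique(cand$read[!uniq])
  structure(out,
            counters = c(reads = n_reads, placed = length(placed_reads),
                         ambiguous = length(ambig_reads),
                         unmapped = n_reads - length(placed_reads) -
                           length(ambig_reads)),
            class = c("read_placements", "data.frame"))
}

# named scaffold vector accessor (internal)
genome_scaffolds <- function(genome) {
  setNames(genome$scaffolds, names(genome$scaffolds))
}

#' Merge unique read placements into conserved-region intervals
#'
#' Unique placements are sorted by (scaffold, start) and merged transitively
#' wherever the gap to the next interval is strictly less than `merge_gap`
#' (a gap of exactly `merge_gap` keeps them separate).
#'
#' @param placements output of [map_reads()].
#' @param merge_gap gap threshold in bases (default 100).
#' @return disjoint, sorted intervals (data frame).
#' @export
placements_to_conserved_bed <- function(placements, merge_gap = 100L) {
  pl <- placements[placements$unique, , drop = FALSE]
  if (nrow(pl) == 0L) return(genomic_intervals())
  merge_intervals(genomic_intervals(pl$scaffold, pl$start, pl$end),
                  merge_gap = merge_gap)
}

#' Remove masked, ambiguous or short conserved regions
#'
#' A region is retained iff its soft-masked (lowercase) fraction is at most
#' `max_masked_frac`, it contains no ambiguous base (`N`/`n`), and its length
#' is at least `min_len`. Input order is preserved.
#'
#' @param intervals data frame of intervals on `base`.
#' @param base the base [genome_assembly()].
#' @param max_masked_frac maximum masked fraction (default 0.25).
#' @param min_len minimum length in bases (default 80).
#' @return the retained intervals.
#' @export
strip_masked_short <- function(intervals, base, max_masked_frac = 0.25,
                               min_len = 80L) {
  if (nrow(intervals) == 0L) return(intervals)
  seqs <- get_sequence(base, intervals$scaffold, intervals$start,
                       intervals$end)
  len <- intervals$end - intervals$start
  keep <- (masked_count(seqs) / len <= max_masked_frac) &
    (ambiguous_count(seqs) == 0L) &
    (len >= min_len)
  intervals[keep, , drop = FALSE]
}
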