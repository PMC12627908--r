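# Interval algebra on 0-based half-open coordinates, backed by
# IRanges/GenomicRanges (converted to 1-based closed internally).

as_granges0 <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$scaffold,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}

as_intervals0 <- function(gr) {
  genomic_intervals(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Merge intervals whose gap is strictly less than `merge_gap`
#'
#' Intervals are sorted by (scaffold, start) and merged transitively whenever
#' the gap between neighbours (`next$start - prev$end`) is strictly less than
#' `merge_gap`; a gap of exactly `merge_gap` keeps them separate. The output is
#' disjoint and sorted.
#'
#' @param intervals a data frame of intervals (0-based half-open).
#' @param merge_gap non-negative integer gap threshold.
#' @return merged, sorted, disjoint intervals.
#' @export
#' @examples
#' iv <- genomic_intervals(c("s1", "s1"), c(0, 149), c(50, 200))
#' merge_intervals(iv, 100)  # gap 99 < 100: one interval [0, 200)
merge_intervals <- function(intervals, merge_gap = 100L) {
  if (nrow(intervals) == 0L) return(genomic_intervals())
  gr <- GenomicRanges::reduce(as_granges0(intervals),
                              min.gapwidth = as.integer(merge_gap))
  out <- as_intervals0(GenomicRanges::sort(gr))
  out[order(out$scaffold, out$start), , drop = FALSE]
}

# Overlap pairs between two interval sets (>= 1 base). Returns a data.frame
# with columns `query` and `subject` (row indices).
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# Pairwise overlap widths (in bases) for matched index pairs.
overlap_width <- function(q, s) {
  pmax(0L, pmin(q$end, s$end) - pmax(q$start, s$start))
}
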