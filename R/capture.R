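# In-silico capture: align a probe set to an assembly, slice matched loci plus
# flanks, and apply the final coverage/identity duplicate screen. The 80/80
# in-silico screen and the 60/60 assembled-contig screen are the same
# operation with different presets.

#' Capture loci from an assembly with a probe set
#'
#' Accepted probe hits (identity at least `align_identity` over at least 50 %
#' of the probe length) are merged per locus into matched regions; each region
#' is extended by `flank` bases on both sides (clipped at scaffold bounds) and
#' sliced. One captured locus is returned per (locus, region).
#'
#' @param probes a `probe_set`.
#' @param assembly the target [genome_assembly()].
#' @param align_identity minimum hit identity (default 0.50).
#' @param flank flank length added on each side (default 400).
#' @param min_cover minimum aligned fraction of the probe (default 0.50).
#' @param index optional precomputed [kmer_index] of `assembly`.
#' @return data frame of class `captured_loci`: `locus_id`, `taxon`,
#'   `scaffold`, `start`, `end` (flank-extended span), `matched_len`,
#'   `identity` (best probe hit), `sequence`.
#' @export
capture <- function(probes, assembly, align_identity = 0.50, flank = 400L,
                    min_cover = 0.50, index = NULL) {
  if (nrow(probes) == 0L) parameter_error("probe set is empty")
  flank <- as.integer(flank)
  hits <- probe_hits(probes$sequence, assembly, min_identity = align_identity,
                     min_cover = min_cover, index = index)
  empty <- structure(data.frame(
    locus_id = character(), taxon = character(), scaffold = character(),
    start = integer(), end = integer(), matched_len = integer(),
    identity = numeric(), sequence = character(), stringsAsFactors = FALSE),
    class = c("captured_loci", "data.frame"))
  if (nrow(hits) == 0L) return(empty)
  hits$locus_id <- probes$locus_id[hits$probe]
  regions <- merge_hit_regions(hits, hits$locus_id)
  lens <- scaffold_lengths(assembly)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    inreg <- hits$locus_id == r$group & hits$scaffold == r$scaffold &
      hits$start < r$end & hits$end > r$start
    s2 <- max(0L, r$start - flank)
    e2 <- min(lens[[r$scaffold]], r$end + flank)
    data.frame(locus_id = r$group, taxon = assembly$taxon,
               scaffold = r$scaffold, start = s2, end = e2,
               matched_len = r$end - r$start,
               identity = max(hits$identity[inreg]),
               sequence = get_sequence(assembly, r$scaffold, s2, e2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$locus_id, out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("captured_loci", "data.frame"))
}

#' Final duplicate screen: match captures back to the probe set
#'
#' Each captured sequence is re-aligned against the probe set. A capture is
#' kept iff its best-matching locus is matched at identity at least
#' `min_identity` with at least `min_coverage` of the probe length aligned,
#' AND the capture-locus assignment is one-to-one: captures matching two or
#' more loci, and loci matched by two or more captures of one taxon, are
#' removed as duplicates.
#'
#' Presets mirror the two published uses: in-silico capture screens at
#' 80 % coverage / 80 % identity, assembled-contig matching at 60 % / 60 %.
#'
#' @param captures a `captured_loci` frame (possibly several taxa).
#' @param probes the `probe_set` to match back against.
#' @param min_coverage,min_identity screen thresholds in (0, 1].
#' @param preset `"insilico"` (0.80/0.80) or `"invitro"` (0.60/0.60);
#'   overridden by explicit thresholds.
#' @return list with elements `kept` (a `captured_loci` frame) and `removed`
#'   (with a `reason` column).
#' @export
dedupe_captures <- function(captures, probes, min_coverage = NULL,
                            min_identity = NULL,
                            preset = c("insilico", "invitro")) {
  preset <- match.arg(preset)
  def <- if (preset == "insilico") 0.80 else 0.60
  min_coverage <- min_coverage %||% def
  min_identity <- min_identity %||% def
  if (min_coverage <= 0 || min_coverage > 1 ||
      min_identity <= 0 || min_identity > 1)
    parameter_error("thresholds must be in (0, 1]")
  if (nrow(captures) == 0L)
    return(list(kept = captures,
                removed = cbind(captures, reason = character())))

  # treat the captured sequences as scaffolds of a pseudo-assembly and match
  # the probes onto them
  cap_ids <- sprintf("cap%d", seq_len(nrow(captures)))
  pseudo <- genome_assembly(setNames(captures$sequence, cap_ids),
                            taxon = "captures")
  hits <- probe_hits(probes$sequence, pseudo, min_identity = min_identity,
                     min_cover = min_coverage)
  match_locus <- vector("list", nrow(captures))
  if (nrow(hits) > 0L) {
    hit_cap <- match(hits$scaffold, cap_ids)
    hit_loc <- probes$locus_id[hits$probe]
    for (i in seq_len(nrow(hits)))
      match_locus[[hit_cap[i]]] <- union(match_locus[[hit_cap[i]]],
                                         hit_loc[i])
  }
  nmatch <- lengths(match_locus)
  reason <- rep(NA_character_, nrow(captures))
  reason[nmatch == 0L] <- "no_match"
  reason[nmatch > 1L] <- "multi_locus"
  best <- ifelse(nmatch == 1L,
                 vapply(match_locus, function(x)
                   if (length(x) == 1L) x else NA_character_, ""),
                 NA_character_)
  # loci matched by >= 2 captures of one taxon: all involved captures removed
  ok <- which(is.na(reason))
  key <- paste(captures$taxon[ok], best[ok])
  dup <- key %in% key[duplicated(key)]
  reason[ok[dup]] <- "locus_collision"
  keep <- is.na(reason)
  removed <- as.data.frame(captures[!keep, , drop = FALSE])
  removed$reason <- reason[!keep]
  list(kept = structure(captures[keep, , drop = FALSE],
                        class = c("captured_loci", "data.frame")),
       removed = removed)
}

#' Per-taxon capture accounting (LE / LR / LRT)
#'
#' @param kept,removed the two elements returned by [dedupe_captures()].
#' @return data frame with columns `taxon`, `loci_extracted`, `loci_removed`,
#'   `loci_retained` (LE, LR, LRT).
#' @export
capture_counts <- function(kept, removed = NULL) {
  taxa <- sort(unique(c(kept$taxon, removed$taxon)))
  le <- vapply(taxa, function(t)
    sum(kept$taxon == t) + sum(removed$taxon == t), 0L)
  lr <- vapply(taxa, function(t) sum(removed$taxon == t), 0L)
  data.frame(taxon = taxa, loci_extracted = le, loci_removed = lr,
             loci_retained = le - lr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a capture-count report as TSV
#'
#' @param counts output of [capture_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_capture_report <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
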