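# Probe-to-genome alignment engine shared by align-back, in-silico capture and
# the capture duplicate screen: exact k-mer seeding on both strands, ungapped
# diagonal verification, and a gapped local alignment fallback
# (Biostrings::pairwiseAlignment) for candidates the ungapped check rejects.

.sub_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Find accepted probe hits on an assembly
#'
#' A hit is accepted when the alignment identity (matches over alignment
#' columns) is at least `min_identity` over at least `min_cover` of the probe
#' length. Candidates come from exact `k`-mer seeds (both strands); each
#' candidate diagonal is first verified ungapped, and only rejected candidates
#' fall through to gapped local alignment.
#'
#' @param sequences character vector of (uppercase) probe sequences.
#' @param genome a [genome_assembly()] (soft-masking ignored for matching).
#' @param min_identity minimum identity in (0, 1].
#' @param min_cover minimum aligned fraction of the probe length.
#' @param k seed length (default 20).
#' @param index optional precomputed [kmer_index] of `genome`.
#' @return data frame with columns `probe` (index into `sequences`),
#'   `scaffold`, `start`, `end` (matched genome span, 0-based half-open),
#'   `strand`, `identity`, `matched_len` (probe bases in the alignment).
#' @export
probe_hits <- function(sequences, genome, min_identity = 0.5,
                       min_cover = 0.5, k = 20L, index = NULL) {
  if (min_identity <= 0 || min_identity > 1)
    parameter_error("min_identity must be in (0, 1]")
  empty <- data.frame(probe = integer(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), matched_len = integer(),
                      stringsAsFactors = FALSE)
  if (length(sequences) == 0L) return(empty)
  if (is.null(index)) index <- kmer_index(genome, k)
  k <- index$k
  scaf_up <- toupper(genome_scaffolds(genome))
  scaf_len <- nchar(scaf_up)
  up <- toupper(sequences)
  res <- list()
  for (w in sort(unique(nchar(up)))) {
    grp <- which(nchar(up) == w)
    if (w < k) next
    hits <- .probe_hits_onewidth(up[grp], w, scaf_up, scaf_len, index,
                                 min_identity, min_cover)
    if (nrow(hits) > 0L) {
      hits$probe <- grp[hits$probe]
      res[[length(res) + 1L]] <- hits
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out[order(out$probe, out$scaffold, out$start), , drop = FALSE]
}

.probe_hits_onewidth <- function(q, w, scaf_up, scaf_len, index,
                                 min_identity, min_cover) {
  k <- index$k
  offs <- unique(c(seq.int(0L, w - k, by = max(1L, as.integer(ceiling(k / 2)))),
                   w - k))
  n <- length(q)
  rc <- revcomp(q)
  gather <- function(qs, strand) {
    codes <- kmer_codes(paste(qs, collapse = ""), k)
    gidx <- rep((seq_len(n) - 1L) * w, each = length(offs)) +
      rep(offs, times = n) + 1L
    h <- kmer_lookup(index, codes[gidx])
    if (nrow(h) == 0L)
      return(data.frame(probe = integer(), scaf = integer(),
                        gstart = integer(), strand = character()))
    probe <- (h$query - 1L) %/% length(offs) + 1L
    off <- offs[(h$query - 1L) %% length(offs) + 1L]
    data.frame(probe = probe, scaf = h$scaf, gstart = h$pos - off,
               strand = strand, stringsAsFactors = FALSE)
  }
  cand <- rbind(gather(q, "+"), gather(rc, "-"))
  if (nrow(cand) == 0L)
    return(data.frame(probe = integer(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), matched_len = integer(),
                      stringsAsFactors = FALSE))
  cand <- cand[!duplicated(cand[c("probe", "scaf", "gstart", "strand")]), ,
               drop = FALSE]
  qs <- ifelse(cand$strand == "+", q[cand$probe], rc[cand$probe])

  # clip candidate windows at scaffold edges; require enough residual span
  lo <- pmax(cand$gstart, 0L)
  hi <- pmin(cand$gstart + w, scaf_len[cand$scaf])
  span <- hi - lo
  ok <- span >= ceiling(min_cover * w)
  cand <- cand[ok, , drop = FALSE]; qs <- qs[ok]
  lo <- lo[ok]; hi <- hi[ok]; span <- span[ok]
  if (nrow(cand) == 0L)
    return(data.frame(probe = integer(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), matched_len = integer(),
                      stringsAsFactors = FALSE))

  # ungapped verification (batched for unclipped candidates)
  accepted <- logical(nrow(cand))
  identity <- numeric(nrow(cand))
  full <- span == w
  if (any(full)) {
    win <- substring(scaf_up[cand$scaf[full]], lo[full] + 1L, hi[full])
    mm <- hamming_batch(qs[full], win, w)
    idy <- (w - mm) / w
    accepted[full] <- idy >= min_identity
    identity[full] <- idy
  }
  if (any(!full)) {
    for (i in which(!full)) {
      qseg <- substring(qs[i], lo[i] - cand$gstart[i] + 1L,
                        hi[i] - cand$gstart[i])
      win <- substring(scaf_up[cand$scaf[i]], lo[i] + 1L, hi[i])
      mm <- hamming_batch(qseg, win, span[i])
      idy <- (span[i] - mm) / span[i]
      if (idy >= min_identity && span[i] >= min_cover * w) {
        accepted[i] <- TRUE; identity[i] <- idy
      }
    }
  }
  out <- data.frame(
    probe = cand$probe, scaffold = names(scaf_up)[cand$scaf],
    start = lo, end = hi, strand = cand$strand,
    identity = identity, matched_len = span,
    stringsAsFactors = FALSE
  )[accepted, , drop = FALSE]

  # gapped fallback for rejected candidates
  fb <- which(!accepted)
  if (length(fb) > 0L) {
    pad <- 25L
    mat <- .sub_mat()
    extra <- lapply(fb, function(i) {
      ws <- max(0L, cand$gstart[i] - pad)
      we <- min(scaf_len[cand$scaf[i]], cand$gstart[i] + w + pad)
      win <- substring(scaf_up[cand$scaf[i]], ws + 1L, we)
      pa <- Biostrings::pairwiseAlignment(qs[i], win, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 2)
      alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (alen == 0L) return(NULL)
      matches <- Biostrings::nmatch(pa)
      pr <- pa@pattern@range
      cov_len <- IRanges::width(pr)
      if (matches / alen < min_identity || cov_len < min_cover * w)
        return(NULL)
      sr <- pa@subject@range
      data.frame(
        probe = cand$probe[i], scaffold = names(scaf_up)[cand$scaf[i]],
        start = ws + IRanges::start(sr) - 1L, end = ws + IRanges::end(sr),
        strand = cand$strand[i], identity = matches / alen,
        matched_len = cov_len, stringsAsFactors = FALSE
      )
    })
    extra <- do.call(rbind, extra)
    if (!is.null(extra)) out <- rbind(out, extra)
  }
  # collapse duplicate/overlapping acceptances of one probe on one diagonal
  out[!duplicated(out[c("probe", "scaffold", "start", "end")]), , drop = FALSE]
}

# Merge a probe-hit frame's intervals per group id into disjoint regions
# (overlapping or bookended hits join). Returns data.frame(group, scaffold,
# start, end).
merge_hit_regions <- function(hits, group) {
  if (nrow(hits) == 0L)
    return(data.frame(group = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  parts <- split(seq_len(nrow(hits)), group)
  out <- lapply(names(parts), function(g) {
    idx <- parts[[g]]
    m <- merge_intervals(genomic_intervals(hits$scaffold[idx],
                                           hits$start[idx], hits$end[idx]),
                         merge_gap = 1L)
    cbind(data.frame(group = g, stringsAsFactors = FALSE), m)
  })
  do.call(rbind, out)
}
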