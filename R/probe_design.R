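# Probe design: extraction of design regions, 120-bp tiling at 3x density,
# GC/mask screening, cross-locus duplicate removal, align-back multi-hit
# filtering with buffered slicing from exemplar genomes, and final
# multi-taxon probe set design.

default_design_params <- function() {
  list(probe_len = 120L, density = 3L, extract_len = 160L, buffer_len = 180L,
       gc_min = 0.30, gc_max = 0.70, mask_max = 0.25,
       alignback_identity = 0.50, dup_identity = 0.50, dup_coverage = 0.50)
}

new_probe_set <- function(df, params = default_design_params()) {
  structure(df, design_params = params,
            class = c("probe_set", "data.frame"))
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d probes, %d loci, %d source taxa\n",
              nrow(x), length(unique(x$locus_id)),
              length(unique(x$source_taxon))))
  invisible(x)
}

#' Extract centered design windows from the base genome
#'
#' For each locus a window of `min(extract_len, locus length)` bases centered
#' on the locus midpoint (left-biased by one base when centering is odd) is
#' sliced from the base genome, then re-filtered by the strip rules (masked
#' fraction > 25 %, any ambiguous base, or length < 80 drop the locus).
#'
#' @param loci a `locus_presence_table`.
#' @param base the base [genome_assembly()].
#' @param extract_len window length (default 160).
#' @param max_masked_frac,min_len strip-rule thresholds.
#' @return data frame of design regions: `locus_id`, `taxon`, `scaffold`,
#'   `start`, `end`, `sequence` (case preserved).
#' @export
extract_design_regions <- function(loci, base, extract_len = 160L,
                                   max_masked_frac = 0.25, min_len = 80L) {
  if (nrow(loci) == 0L)
    return(data.frame(locus_id = character(), taxon = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  len <- loci$end - loci$start
  w <- pmin(as.integer(extract_len), len)
  wstart <- loci$start + (len - w) %/% 2L
  seqs <- get_sequence(base, loci$scaffold, wstart, wstart + w)
  keep <- (masked_count(seqs) / w <= max_masked_frac) &
    (ambiguous_count(seqs) == 0L) & (w >= min_len)
  data.frame(locus_id = loci$locus_id[keep], taxon = base$taxon,
             scaffold = loci$scaffold[keep], start = wstart[keep],
             end = (wstart + w)[keep], sequence = seqs[keep],
             stringsAsFactors = FALSE)
}

#' Tile probes across design regions
#'
#' Tile step is `probe_len / density` (integer division; 120/3 = 40). Probe
#' starts are the multiples of the step that fit, plus the anchored final
#' start `L - probe_len` when not already present, so a 160-bp locus yields
#' two probes overlapping its middle by 40 bp. Probe sequences are uppercased;
#' soft-mask and ambiguity counts of the source window are carried alongside
#' for the downstream screens. Regions shorter than `probe_len` are skipped
#' with a warning.
#'
#' @param regions design regions (from [extract_design_regions()] or
#'   [alignback_and_slice()]; needs columns `locus_id`, `taxon`, `scaffold`,
#'   `start`, `sequence`).
#' @param probe_len probe length (default 120); must be divisible by
#'   `density`.
#' @param density tiling density (default 3).
#' @return a `probe_set` data frame: `locus_id`, `source_taxon`, `tile_index`,
#'   `sequence` (uppercase), `masked`, `ambiguous`, `scaffold`, `start`,
#'   `end`.
#' @export
tile_probes <- function(regions, probe_len = 120L, density = 3L) {
  probe_len <- as.integer(probe_len); density <- as.integer(density)
  if (probe_len %% density != 0L)
    parameter_error("probe_len must be divisible by density")
  step <- probe_len %/% density
  L <- nchar(regions$sequence)
  short <- L < probe_len
  if (any(short)) {
    warning(sprintf("%d region(s) shorter than probe length %d skipped",
                    sum(short), probe_len), call. = FALSE)
    regions <- regions[!short, , drop = FALSE]
    L <- L[!short]
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    starts <- seq.int(0L, L[i] - probe_len, by = step)
    anchor <- L[i] - probe_len
    if (!anchor %in% starts) starts <- c(starts, anchor)
    raw <- substring(regions$sequence[i], starts + 1L, starts + probe_len)
    data.frame(
      locus_id = regions$locus_id[i],
      source_taxon = regions$taxon[i],
      tile_index = seq_along(starts) - 1L,
      sequence = toupper(raw),
      masked = masked_count(raw),
      ambiguous = ambiguous_count(raw) > 0L,
      scaffold = regions$scaffold[i],
      start = regions$start[i] + starts,
      end = regions$start[i] + starts + probe_len,
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else data.frame(
    locus_id = character(), source_taxon = character(),
    tile_index = integer(), sequence = character(), masked = integer(),
    ambiguous = logical(), scaffold = character(), start = integer(),
    end = integer(), stringsAsFactors = FALSE)
  new_probe_set(df, within_params(probe_len = probe_len, density = density))
}

within_params <- function(...) {
  p <- default_design_params()
  args <- list(...)
  p[names(args)] <- args
  p
}

#' Screen probes for GC content, masked bases and ambiguity
#'
#' A probe is kept iff its masked fraction is at most `mask_max`, its GC
#' fraction (over all probe bases) lies in `[gc_min, gc_max]`, and it contains
#' no ambiguous base.
#'
#' @param probes a `probe_set`.
#' @param gc_min,gc_max GC bounds (defaults 0.30 and 0.70, inclusive).
#' @param mask_max maximum soft-masked fraction (default 0.25).
#' @return list with elements `kept` (a `probe_set`) and `dropped` (data frame
#'   with a `reason` column).
#' @export
screen_probes <- function(probes, gc_min = 0.30, gc_max = 0.70,
                          mask_max = 0.25) {
  plen <- nchar(probes$sequence)
  gc <- gc_fraction(probes$sequence)
  mfrac <- probes$masked / plen
  reason <- rep(NA_character_, nrow(probes))
  reason[probes$ambiguous] <- "ambiguous"
  reason[is.na(reason) & mfrac > mask_max] <- "masked"
  reason[is.na(reason) & (gc < gc_min | gc > gc_max)] <- "gc"
  keep <- is.na(reason)
  dropped <- probes[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  params <- attr(probes, "design_params") %||% default_design_params()
  params$gc_min <- gc_min; params$gc_max <- gc_max; params$mask_max <- mask_max
  list(kept = new_probe_set(probes[keep, , drop = FALSE], params),
       dropped = as.data.frame(dropped))
}

# candidate cross-locus probe pairs sharing an exact prefilter k-mer
.shared_kmer_pairs <- function(seqs, locus, k) {
  n <- length(seqs)
  codes_of <- function(x) {
    lapply(x, function(s) unique(kmer_codes(s, k)))
  }
  fwd <- codes_of(seqs)
  rc <- codes_of(revcomp(seqs))
  df <- data.frame(
    code = c(unlist(fwd), unlist(rc)),
    probe = c(rep(seq_len(n), lengths(fwd)), rep(seq_len(n), lengths(rc))),
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$code), , drop = FALSE]
  df <- df[!duplicated(df[c("code", "probe")]), , drop = FALSE]
  groups <- split(df$probe, df$code)
  groups <- groups[lengths(groups) > 1L]
  pairs <- unique(do.call(rbind, lapply(groups, function(g) {
    g <- sort(unique(g))
    if (length(g) < 2L) return(NULL)
    t(utils::combn(g, 2L))
  })))
  if (is.null(pairs))
    return(data.frame(a = integer(), b = integer()))
  pairs <- as.data.frame(pairs); names(pairs) <- c("a", "b")
  pairs[locus[pairs$a] != locus[pairs$b], , drop = FALSE]
}

#' Remove loci whose probes cross-match other loci
#'
#' All-versus-all comparison between probes of different loci (shared-k-mer
#' prefilter, then gapped local alignment). If any cross-locus probe pair
#' aligns with identity at least `identity_threshold` over at least
#' `coverage_threshold` of the probe length, both loci are flagged and all
#' their probes removed. Within-locus overlaps never count.
#'
#' @param probes a `probe_set`.
#' @param identity_threshold,coverage_threshold duplicate-call thresholds
#'   (defaults 0.50 / 0.50).
#' @param prefilter_k shared-k-mer prefilter length (default 14).
#' @return the filtered `probe_set`; removed locus ids in attribute
#'   `removed_loci`.
#' @export
remove_duplicate_loci <- function(probes, identity_threshold = 0.50,
                                  coverage_threshold = 0.50,
                                  prefilter_k = 14L) {
  if (nrow(probes) == 0L) return(probes)
  seqs <- toupper(probes$sequence)
  pairs <- .shared_kmer_pairs(seqs, probes$locus_id, prefilter_k)
  flagged <- character()
  if (nrow(pairs) > 0L) {
    # collapse to one candidate pair per locus pair, preferring any pair
    key <- paste(pmin(probes$locus_id[pairs$a], probes$locus_id[pairs$b]),
                 pmax(probes$locus_id[pairs$a], probes$locus_id[pairs$b]))
    mat <- .sub_mat()
    for (kk in unique(key)) {
      rows <- which(key == kk)
      hit <- FALSE
      for (r in rows) {
        a <- seqs[pairs$a[r]]; b <- seqs[pairs$b[r]]
        plen <- nchar(a)
        for (bb in c(b, revcomp(b))) {
          pa <- Biostrings::pairwiseAlignment(a, bb, type = "local",
                                              substitutionMatrix = mat,
                                              gapOpening = 5,
                                              gapExtension = 2)
          alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
          if (alen == 0L) next
          cov <- IRanges::width(pa@pattern@range)
          if (Biostrings::nmatch(pa) / alen >= identity_threshold &&
              cov >= coverage_threshold * plen) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (hit)
        flagged <- union(flagged, c(probes$locus_id[pairs$a[rows[1]]],
                                    probes$locus_id[pairs$b[rows[1]]]))
    }
  }
  kept <- new_probe_set(probes[!probes$locus_id %in% flagged, , drop = FALSE],
                        attr(probes, "design_params") %||%
                          default_design_params())
  attr(kept, "removed_loci") <- flagged
  kept
}

#' Align probes back to all genomes, drop multi-hit loci, slice buffered loci
#'
#' Each probe is aligned to each genome (k-mer seeded, gapped local fallback);
#' hits are accepted at identity at least `identity` over at least 50 % of the
#' probe length. A probe with accepted hits at more than one distinct
#' (non-overlapping) genomic region in any genome is removed along with its
#' whole locus. For every surviving (locus, taxon) the span of that locus's
#' probe hits is extended symmetrically to `buffer_len` (clipped at scaffold
#' ends, kept at reduced length and flagged) and sliced from the genome.
#'
#' @param temp_probes a screened `probe_set`.
#' @param genomes named list (taxon -> [genome_assembly()]), typically base
#'   plus exemplars.
#' @param identity align-back identity (default 0.50).
#' @param buffer_len slice length (default 180).
#' @param min_cover minimum aligned fraction of the probe (default 0.50).
#' @param indexes optional named list of precomputed [kmer_index] objects.
#' @return a `locus_slices` data frame: `locus_id`, `taxon`, `scaffold`,
#'   `start`, `end`, `sequence` (case preserved), `clipped`; removed locus ids
#'   in attribute `removed_loci`.
#' @export
alignback_and_slice <- function(temp_probes, genomes, identity = 0.50,
                                buffer_len = 180L, min_cover = 0.50,
                                indexes = NULL) {
  if (!is.list(genomes) || is.null(names(genomes)) ||
      !all(vapply(genomes, inherits, TRUE, "genome_assembly")))
    parameter_error("genomes must be a named list of genome_assembly objects")
  buffer_len <- as.integer(buffer_len)
  all_hits <- list()
  multi <- character()
  for (tx in names(genomes)) {
    hits <- probe_hits(temp_probes$sequence, genomes[[tx]],
                       min_identity = identity, min_cover = min_cover,
                       index = indexes[[tx]])
    if (nrow(hits) == 0L) next
    regions <- merge_hit_regions(hits, as.character(hits$probe))
    nreg <- table(regions$group)
    multi <- union(multi,
                   unique(temp_probes$locus_id[
                     as.integer(names(nreg)[nreg > 1L])]))
    hits$taxon <- tx
    hits$locus_id <- temp_probes$locus_id[hits$probe]
    all_hits[[tx]] <- hits
  }
  hits <- do.call(rbind, all_hits)
  slices_empty <- structure(data.frame(
    locus_id = character(), taxon = character(), scaffold = character(),
    start = integer(), end = integer(), sequence = character(),
    clipped = logical(), stringsAsFactors = FALSE),
    removed_loci = multi, class = c("locus_slices", "data.frame"))
  if (is.null(hits) || nrow(hits) == 0L) return(slices_empty)
  hits <- hits[!hits$locus_id %in% multi, , drop = FALSE]
  if (nrow(hits) == 0L) return(slices_empty)

  key <- paste(hits$locus_id, hits$taxon, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    # keep the scaffold carrying the most probe hits (ties: first)
    scf <- names(sort(table(h$scaffold), decreasing = TRUE))[1]
    h <- h[h$scaffold == scf, , drop = FALSE]
    s <- min(h$start); e <- max(h$end)
    tx <- h$taxon[1]
    L <- scaffold_lengths(genomes[[tx]])[scf]
    pad <- buffer_len - (e - s)
    if (pad > 0L) {
      s2 <- s - pad %/% 2L
      e2 <- e + (pad - pad %/% 2L)
    } else { s2 <- s; e2 <- e }
    s2c <- max(0L, s2); e2c <- min(L, e2)
    data.frame(locus_id = h$locus_id[1], taxon = tx, scaffold = scf,
               start = s2c, end = e2c,
               sequence = get_sequence(genomes[[tx]], scf, s2c, e2c),
               clipped = (s2c != s2) || (e2c != e2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$locus_id, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, removed_loci = multi,
            class = c("locus_slices", "data.frame"))
}

#' Design the final multi-taxon probe set from buffered slices
#'
#' Loci with slices from at least `min_exemplars` distinct taxa are retained;
#' probes are tiled from every retained taxon's slice of each locus, screened
#' for GC/mask, exact-duplicate probe sequences across taxa collapse to one,
#' and cross-locus duplicates are removed.
#'
#' @param slices a `locus_slices` frame from [alignback_and_slice()].
#' @param min_exemplars minimum number of taxa with a slice.
#' @param probe_len,density,gc_min,gc_max,mask_max tiling/screen parameters.
#' @param dup_identity,dup_coverage cross-locus duplicate thresholds.
#' @return the final `probe_set`; per-stage counts in attribute `report`.
#' @export
design_final_set <- function(slices, min_exemplars, probe_len = 120L,
                             density = 3L, gc_min = 0.30, gc_max = 0.70,
                             mask_max = 0.25, dup_identity = 0.50,
                             dup_coverage = 0.50) {
  n_taxa <- length(unique(slices$taxon))
  if (min_exemplars > max(n_taxa, 1L))
    parameter_error("min_exemplars exceeds the number of taxa with slices")
  per_locus <- tapply(slices$taxon, slices$locus_id,
                      function(t) length(unique(t)))
  keep_loci <- names(per_locus)[per_locus >= min_exemplars]
  sl <- slices[slices$locus_id %in% keep_loci, , drop = FALSE]
  if (nrow(sl) == 0L) {
    ps <- new_probe_set(tile_probes(sl[0, ], probe_len, density))
    attr(ps, "report") <- c(loci_in = length(per_locus), loci_kept = 0L,
                            tiled = 0L, screened = 0L, deduped = 0L)
    return(ps)
  }
  tiled <- suppressWarnings(tile_probes(sl, probe_len, density))
  scr <- screen_probes(tiled, gc_min, gc_max, mask_max)
  kept <- scr$kept
  # exact duplicate sequences across taxa collapse to one
  kept <- kept[!duplicated(toupper(kept$sequence)), , drop = FALSE]
  final <- remove_duplicate_loci(new_probe_set(kept,
                                               attr(scr$kept, "design_params")),
                                 dup_identity, dup_coverage)
  attr(final, "report") <- c(loci_in = length(per_locus),
                             loci_kept = length(keep_loci),
                             tiled = nrow(tiled), screened = nrow(scr$kept),
                             deduped = nrow(final))
  final
}
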