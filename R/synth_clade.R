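# Synthetic clades with planted conserved elements: a uniform-random ancestral
# genome receives non-overlapping core+flank regions; sequences evolve down an
# ultrametric tree under a Jukes-Cantor-style substitution process whose
# per-site substitution probability is branch_length * background_rate,
# multiplied by core_rate_scale inside cores. Soft-masking and N characters
# are applied to background only (never inside cores), at identical positions
# in every taxon (repeats conserved in location), so planted coordinates stay
# comparable across taxa.

# balanced binary topology over n labels as a newick string
.balanced_newick <- function(labels) {
  build <- function(lb) {
    if (length(lb) == 1L) return(lb)
    h <- ceiling(length(lb) / 2)
    paste0("(", build(lb[seq_len(h)]), ",",
           build(lb[-seq_len(h)]), ")")
  }
  paste0(build(labels), ";")
}

#' Generate a synthetic clade with planted conserved cores
#'
#' @param n_taxa number of leaf genomes (default 6).
#' @param genome_len genome length in bases (one scaffold per taxon).
#' @param n_loci number of planted core+flank regions.
#' @param core_len conserved-core length (default 160).
#' @param flank_len variable-flank length on each side (default 400).
#' @param tree optional newick string or `phylo` with `n_taxa` leaves and
#'   branch lengths; default is a balanced tree of unit depth (Grafen branch
#'   lengths).
#' @param background_rate expected substitutions/site per unit branch length
#'   in background and flanks (default 0.30).
#' @param core_rate_scale multiplier on the substitution probability inside
#'   cores, in `[0, 1)` (default 0.05).
#' @param mask_fraction fraction of background soft-masked (default 0.10).
#' @param n_fraction fraction of background bases replaced by `N`
#'   (default 0.001).
#' @param seed integer seed; the run is deterministic given `seed`.
#' @return list with `genomes` (named list of [genome_assembly()]) and `truth`
#'   (a `truth_manifest`: planted-locus coordinates — valid in every taxon
#'   since evolution is substitution-only — the tree in newick, and all
#'   generator parameters).
#' @export
generate_clade <- function(n_taxa = 6L, genome_len = 1e6, n_loci = 300L,
                           core_len = 160L, flank_len = 400L, tree = NULL,
                           background_rate = 0.30, core_rate_scale = 0.05,
                           mask_fraction = 0.10, n_fraction = 0.001,
                           seed = 1L) {
  genome_len <- as.integer(genome_len)
  region_len <- core_len + 2L * flank_len
  if (n_loci * region_len > genome_len / 2)
    parameter_error("infeasible packing: n_loci * (core + 2*flank) exceeds half the genome")
  min_sep <- core_len
  if (n_loci * region_len + (n_loci - 1L) * min_sep > genome_len)
    parameter_error("infeasible packing with required separation")
  if (core_rate_scale < 0 || core_rate_scale >= 1)
    parameter_error("core_rate_scale must be in [0, 1)")
  taxa <- sprintf("t%d", seq_len(n_taxa))
  phy <- if (is.null(tree)) {
    ape::compute.brlen(ape::read.tree(text = .balanced_newick(taxa)),
                       method = "Grafen")
  } else if (inherits(tree, "phylo")) tree
  else ape::read.tree(text = tree)
  if (ape::Ntip(phy) != n_taxa)
    parameter_error("tree must have n_taxa leaves")
  if (is.null(phy$edge.length))
    parameter_error("tree must have branch lengths")
  taxa <- phy$tip.label

  with_seed(seed, {
    # place non-overlapping regions with >= core_len separation
    slack <- genome_len - n_loci * region_len - (n_loci - 1L) * min_sep
    u <- sort(floor(runif(n_loci, 0, slack + 1)))
    region_start <- as.integer(u + (seq_len(n_loci) - 1L) *
                                 (region_len + min_sep))
    core_start <- region_start + flank_len
    core <- logical(genome_len)
    for (i in seq_len(n_loci))
      core[(core_start[i] + 1L):(core_start[i] + core_len)] <- TRUE

    ancestor <- sample.int(4L, genome_len, replace = TRUE) - 1L
    rate_scale <- ifelse(core, core_rate_scale, 1)

    # evolve down the tree (cladewise edge order is root-first)
    nseq <- vector("list", ape::Ntip(phy) + phy$Nnode)
    root <- ape::Ntip(phy) + 1L
    nseq[[root]] <- ancestor
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      p <- pmin(1, phy$edge.length[e] * background_rate * rate_scale)
      s <- nseq[[parent]]
      idx <- which(runif(genome_len) < p)
      if (length(idx))
        s[idx] <- (s[idx] + sample.int(3L, length(idx), replace = TRUE)) %% 4L
      nseq[[child]] <- s
    }

    # background mask runs (mean length 50) and scattered N positions,
    # identical across taxa, never inside cores
    bg <- which(!core)
    mask <- logical(genome_len)
    target <- round(mask_fraction * length(bg))
    guard <- 0L
    while (sum(mask) < target && guard < 200L) {
      m <- max(8L, ceiling((target - sum(mask)) / 50))
      starts <- sample(bg, m)
      lens <- stats::rgeom(m, 1 / 50) + 1L
      for (i in seq_len(m)) {
        span <- starts[i]:min(genome_len, starts[i] + lens[i] - 1L)
        mask[span] <- TRUE
      }
      mask[core] <- FALSE
      guard <- guard + 1L
    }
    npos <- sample(bg, round(n_fraction * length(bg)))

    bases <- c("A", "C", "G", "T")
    genomes <- lapply(seq_along(taxa), function(i) {
      tip <- which(phy$tip.label == taxa[i])
      ch <- bases[nseq[[tip]] + 1L]
      ch[npos] <- "N"
      ch[mask] <- tolower(ch[mask])
      genome_assembly(setNames(paste(ch, collapse = ""), "scaf1"),
                      taxon = taxa[i])
    })
    names(genomes) <- taxa

    planted <- data.frame(
      locus_id = sprintf("planted-%d", seq_len(n_loci)),
      scaffold = "scaf1",
      core_start = core_start, core_end = core_start + core_len,
      region_start = region_start, region_end = region_start + region_len,
      stringsAsFactors = FALSE
    )
    truth <- structure(
      list(planted = planted, taxa = taxa,
           tree = ape::write.tree(phy),
           core_len = as.integer(core_len), flank_len = as.integer(flank_len),
           params = list(genome_len = genome_len, n_loci = n_loci,
                         background_rate = background_rate,
                         core_rate_scale = core_rate_scale,
                         mask_fraction = mask_fraction,
                         n_fraction = n_fraction, seed = seed)),
      class = "truth_manifest")
    list(genomes = genomes, truth = truth)
  })
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("<truth_manifest> %d planted loci (core %d bp, flank %d bp), %d taxa\n",
              nrow(x$planted), x$core_len, x$flank_len, length(x$taxa)))
  invisible(x)
}

#' Score locus recovery against the planted ground truth
#'
#' A planted locus counts as recovered iff some reported locus overlaps its
#' core by at least half the core length; reported loci overlapping no planted
#' core count as false loci.
#'
#' @param truth a `truth_manifest`.
#' @param loci reported loci: a `locus_presence_table`, `captured_loci`, or
#'   any data frame with `scaffold`, `start`, `end`.
#' @return list with `sensitivity`, `false_loci`, `n_planted`, `n_reported`
#'   and the logical vector `recovered`.
#' @export
score_recovery <- function(truth, loci) {
  cores <- genomic_intervals(truth$planted$scaffold,
                             truth$planted$core_start,
                             truth$planted$core_end)
  n_planted <- nrow(cores)
  if (nrow(loci) == 0L)
    return(list(sensitivity = 0, false_loci = 0L, n_planted = n_planted,
                n_reported = 0L, recovered = rep(FALSE, n_planted)))
  rep_iv <- genomic_intervals(loci$scaffold, loci$start, loci$end)
  ov <- interval_overlaps(cores, rep_iv)
  w <- overlap_width(cores[ov$query, , drop = FALSE],
                     rep_iv[ov$subject, , drop = FALSE])
  recovered <- rep(FALSE, n_planted)
  good <- ov$query[w >= truth$core_len / 2]
  recovered[unique(good)] <- TRUE
  false_loci <- nrow(rep_iv) - length(unique(ov$subject))
  list(sensitivity = mean(recovered), false_loci = false_loci,
       n_planted = n_planted, n_reported = nrow(rep_iv),
       recovered = recovered)
}

#' Write a truth manifest as TSV (+ newick tree alongside)
#'
#' @param truth a `truth_manifest`.
#' @param path output TSV path; the tree is written to `<path>.nwk`.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  write.table(truth$planted, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(truth$tree, paste0(path, ".nwk"))
  invisible(path)
}
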