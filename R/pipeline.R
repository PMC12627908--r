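# End-to-end orchestration: discovery (simulate -> map -> merge -> strip ->
# presence table), design (+k selection -> extraction -> tiling -> screens ->
# align-back -> final set), self-capture, and the base-genome x exemplar-count
# sweep.
#
# The discovery default coverage is 20x, not the 2x default of
# simulate_read_pairs(): with 100-bp reads and 160-bp cores only reads fully
# nested in a core can pass the 5 % mismatch cap (flanks are diverged), so the
# window of mappable read starts per core is core_len - read_len + 1 = 61 bp.
# At depth c the expected number of such reads per exemplar is c*61/200;
# requiring every exemplar to detect nearly every core (joint detection across
# 5 exemplars ~0.98 per locus) needs about 4-6 expected reads, i.e. 15-20x.
# Error-free in-silico reads are cheap, so the pipeline defaults to 20x.

#' Discover conserved loci shared between a base genome and exemplars
#'
#' Simulates error-free paired-end reads from each exemplar genome, maps them
#' to the base genome at the divergence tolerance, merges unique placements
#' into conserved intervals, strips masked/ambiguous/short regions, and builds
#' the shared-locus presence table.
#'
#' @param genomes named list (taxon -> [genome_assembly()]).
#' @param base_taxon which genome is the base (coordinates of the table).
#' @param exemplars exemplar taxa; default all non-base genomes.
#' @param coverage read-simulation depth for discovery (default 20; see
#'   Details in the package vignette).
#' @param read_len,frag_mean,frag_sd read-simulation parameters.
#' @param max_divergence,seed_kmer mapping parameters.
#' @param merge_gap,max_masked_frac,min_len interval merge/strip parameters.
#' @param seed master seed; per-exemplar simulation seeds are derived from it.
#' @return list with `table` (a `locus_presence_table`), `beds` (named list of
#'   per-exemplar conserved intervals), and `counters` (per-exemplar mapping
#'   counts).
#' @export
uce_discover <- function(genomes, base_taxon, exemplars = NULL,
                         coverage = 20, read_len = 100L, frag_mean = 250L,
                         frag_sd = 50, max_divergence = 0.05,
                         seed_kmer = 20L, merge_gap = 100L,
                         max_masked_frac = 0.25, min_len = 80L, seed = 1L) {
  if (!base_taxon %in% names(genomes))
    parameter_error(sprintf("base taxon '%s' not among genomes", base_taxon))
  exemplars <- exemplars %||% setdiff(names(genomes), base_taxon)
  base <- genomes[[base_taxon]]
  index <- kmer_index(base, seed_kmer)
  beds <- list(); counters <- list()
  for (tx in exemplars) {
    pairs <- simulate_read_pairs(genomes[[tx]], read_len = read_len,
                                 coverage = coverage, frag_mean = frag_mean,
                                 frag_sd = frag_sd,
                                 seed = derive_seed(seed, tx))
    pl <- map_reads(pairs, base, max_divergence = max_divergence,
                    seed_kmer = seed_kmer, index = index)
    bed <- placements_to_conserved_bed(pl, merge_gap = merge_gap)
    bed <- strip_masked_short(bed, base, max_masked_frac = max_masked_frac,
                              min_len = min_len)
    beds[[tx]] <- bed
    counters[[tx]] <- attr(pl, "counters")
  }
  counters <- data.frame(taxon = exemplars,
                         do.call(rbind, counters), row.names = NULL)
  list(table = build_presence_table(beds, base, merge_gap = merge_gap),
       beds = beds, counters = counters)
}

#' Design a probe set from a presence table
#'
#' Applies "+k" selection, extracts centered design windows from the base
#' genome, tiles and screens temporary probes, removes cross-locus duplicate
#' loci, aligns the temporary set back to all genomes (removing multi-hit
#' loci), slices buffered loci from every genome, and designs the final
#' multi-taxon probe set.
#'
#' @param table a `locus_presence_table`.
#' @param genomes named list (taxon -> [genome_assembly()]), base included.
#' @param base_taxon the base taxon label.
#' @param min_exemplars "+k" selection level (and the minimum number of taxa
#'   with a slice for the final set).
#' @param extract_len,probe_len,density,buffer_len design geometry.
#' @param gc_min,gc_max,mask_max probe screen thresholds.
#' @param alignback_identity align-back identity (default 0.50).
#' @param dup_identity,dup_coverage cross-locus duplicate thresholds.
#' @param indexes optional named list of precomputed [kmer_index] objects for
#'   `genomes` (reused across sweep cells).
#' @return list with `probes` (final `probe_set`), `temp_probes`, `slices`,
#'   and a named `report` vector of per-stage counts.
#' @export
uce_design <- function(table, genomes, base_taxon, min_exemplars,
                       extract_len = 160L, probe_len = 120L, density = 3L,
                       buffer_len = 180L, gc_min = 0.30, gc_max = 0.70,
                       mask_max = 0.25, alignback_identity = 0.50,
                       dup_identity = 0.50, dup_coverage = 0.50,
                       indexes = NULL) {
  base <- genomes[[base_taxon]]
  if (is.null(base)) parameter_error("base taxon not among genomes")
  sel <- select_shared(table, min_exemplars)
  regions <- extract_design_regions(sel, base, extract_len = extract_len)
  tiled <- suppressWarnings(tile_probes(regions, probe_len, density))
  scr <- screen_probes(tiled, gc_min, gc_max, mask_max)
  temp <- remove_duplicate_loci(scr$kept, dup_identity, dup_coverage)
  slices <- alignback_and_slice(temp, genomes, identity = alignback_identity,
                                buffer_len = buffer_len, indexes = indexes)
  final <- design_final_set(slices, min_exemplars, probe_len = probe_len,
                            density = density, gc_min = gc_min,
                            gc_max = gc_max, mask_max = mask_max,
                            dup_identity = dup_identity,
                            dup_coverage = dup_coverage)
  report <- c(table_loci = nrow(table), selected_loci = nrow(sel),
              design_regions = nrow(regions), temp_probes = nrow(temp),
              temp_loci = length(unique(temp$locus_id)),
              final_probes = nrow(final),
              final_loci = length(unique(final$locus_id)))
  list(probes = final, temp_probes = temp, slices = slices, report = report)
}

#' Capture a probe set against several assemblies and dedupe
#'
#' @param probes a `probe_set`.
#' @param genomes named list of assemblies to capture against.
#' @param align_identity,flank capture parameters.
#' @param preset,min_coverage,min_identity duplicate-screen parameters (see
#'   [dedupe_captures()]).
#' @param indexes optional named list of precomputed [kmer_index] objects.
#' @return list with `kept`, `removed`, `counts` (LE/LR/LRT per taxon) and
#'   `unique_loci` (distinct retained locus ids across all taxa).
#' @export
capture_all <- function(probes, genomes, align_identity = 0.50, flank = 400L,
                        preset = "insilico", min_coverage = NULL,
                        min_identity = NULL, indexes = NULL) {
  caps <- lapply(names(genomes), function(tx)
    capture(probes, genomes[[tx]], align_identity = align_identity,
            flank = flank, index = indexes[[tx]]))
  caps <- do.call(rbind, caps)
  caps <- structure(caps, class = c("captured_loci", "data.frame"))
  dd <- dedupe_captures(caps, probes, min_coverage = min_coverage,
                        min_identity = min_identity, preset = preset)
  list(kept = dd$kept, removed = dd$removed,
       counts = capture_counts(dd$kept, dd$removed),
       unique_loci = length(unique(dd$kept$locus_id)))
}

#' Run the base-genome x exemplar-count sweep
#'
#' For each (base, k) cell: discovery and design with that base and
#' `min_exemplars = k` over all remaining non-outgroup taxa, followed by
#' self-capture of the final set against every exemplar (outgroups included in
#' capture but excluded from discovery/design). A k exceeding the exemplar
#' count yields a cell with zero loci (no locus can be detected in more
#' exemplars than exist); a stage error marks the cell failed and the sweep
#' continues. Discovery is computed once per base and shared across its k
#' cells (cells stay independent in value).
#'
#' @param genomes named list (taxon -> [genome_assembly()]).
#' @param base_taxa base genomes to sweep over.
#' @param k_values exemplar-count selection levels.
#' @param outgroups taxa excluded from discovery/design, included in capture.
#' @param coverage discovery read depth (default 20).
#' @param seed master seed.
#' @param ... further parameters passed to [uce_discover()] / [uce_design()].
#' @return data frame, one row per (base, k): stage counts, in-silico unique
#'   loci after self-capture, and a `status` column.
#' @export
run_sweep <- function(genomes, base_taxa, k_values, outgroups = character(),
                      coverage = 20, seed = 1L, ...) {
  if (!all(base_taxa %in% names(genomes)))
    parameter_error("every base taxon must be among the genomes")
  dots <- list(...)
  pick <- function(f) dots[names(dots) %in% names(formals(f))]
  rows <- list()
  for (base in base_taxa) {
    exemplars <- setdiff(names(genomes), c(base, outgroups))
    design_genomes <- genomes[c(base, exemplars)]
    disc <- tryCatch(
      do.call(uce_discover, c(list(genomes, base, exemplars = exemplars,
                                   coverage = coverage, seed = seed),
                              pick(uce_discover))),
      uceforge_error = function(e) e)
    indexes <- if (!inherits(disc, "error"))
      lapply(genomes, kmer_index) else NULL
    for (k in k_values) {
      row <- data.frame(base = base, k = k, table_loci = NA_integer_,
                        selected_loci = NA_integer_,
                        temp_probes = NA_integer_, temp_loci = NA_integer_,
                        final_probes = NA_integer_, final_loci = NA_integer_,
                        insilico_unique_loci = NA_integer_,
                        status = "failed", stringsAsFactors = FALSE)
      if (inherits(disc, "error")) {
        rows[[length(rows) + 1L]] <- row
        next
      }
      row$table_loci <- nrow(disc$table)
      if (k > length(exemplars)) {
        row[c("selected_loci", "temp_probes", "temp_loci", "final_probes",
              "final_loci", "insilico_unique_loci")] <- 0L
        row$status <- "k_exceeds_exemplars"
        rows[[length(rows) + 1L]] <- row
        next
      }
      cell <- tryCatch({
        des <- do.call(uce_design,
                       c(list(disc$table, design_genomes, base, k,
                              indexes = indexes[names(design_genomes)]),
                         pick(uce_design)))
        isu <- if (nrow(des$probes) > 0L)
          capture_all(des$probes, genomes,
                      indexes = indexes)$unique_loci else 0L
        r <- des$report
        row[c("selected_loci", "temp_probes", "temp_loci", "final_probes",
              "final_loci")] <-
          as.integer(r[c("selected_loci", "temp_probes", "temp_loci",
                         "final_probes", "final_loci")])
        row$insilico_unique_loci <- isu
        row$status <- "ok"
        row
      }, error = function(e) row)
      rows[[length(rows) + 1L]] <- cell
    }
  }
  do.call(rbind, rows)
}
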