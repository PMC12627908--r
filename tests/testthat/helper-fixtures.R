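# Fixture builders shared across test files. All fixtures are generated in
# code; the heavyweight clade pipeline is computed once per test run and
# memoised.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else uceforge:::with_seed(seed, draw())
}

random_genome <- function(len, taxon = "t", seed = 1, scaffold = "s1") {
  genome_assembly(setNames(random_dna(len, seed), scaffold), taxon = taxon)
}

# mutate `n_mut` distinct positions of a sequence (always to a different base)
mutate_seq <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A", a = "c", c = "g", g = "t",
           t = "a")
  ch[positions] <- rot[ch[positions]]
  paste(ch, collapse = "")
}

# a minimal probe_set data frame around explicit sequences
probe_frame <- function(sequences, locus_id, taxon = "t1",
                        tile_index = NULL, masked = 0L) {
  n <- length(sequences)
  if (is.null(tile_index)) tile_index <- seq_len(n) - 1L
  uceforge:::new_probe_set(data.frame(
    locus_id = rep_len(locus_id, n),
    source_taxon = rep_len(taxon, n),
    tile_index = tile_index,
    sequence = toupper(sequences),
    masked = rep_len(masked, n),
    ambiguous = uceforge:::ambiguous_count(sequences) > 0L,
    scaffold = "s1",
    start = 0L,
    end = nchar(sequences),
    stringsAsFactors = FALSE
  ))
}

# The study-condition clade pipeline (6 taxa, 1 Mb, 300 planted cores,
# core_rate_scale 0.05, background 0.30, seed 7), run once per test session.
clade_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cl <- generate_clade(n_taxa = 6, genome_len = 1e6, n_loci = 300,
                         core_rate_scale = 0.05, background_rate = 0.30,
                         seed = 7)
    disc <- uce_discover(cl$genomes, "t1", seed = 7)
    indexes <- lapply(cl$genomes, uceforge:::kmer_index)
    des5 <- uce_design(disc$table, cl$genomes, "t1", min_exemplars = 5,
                       indexes = indexes)
    des2 <- uce_design(disc$table, cl$genomes, "t1", min_exemplars = 2,
                       indexes = indexes)
    caps <- capture_all(des5$probes, cl$genomes, indexes = indexes)
    cache <<- list(clade = cl, disc = disc, des5 = des5, des2 = des2,
                   caps = caps)
    cache
  }
})
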