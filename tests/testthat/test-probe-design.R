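# Probe design: extraction geometry, tiling rule, GC/mask screens, duplicate
# locus removal (with a brute-force alignment oracle), align-back and slicing.

make_table <- function(starts, ends, scaffold = "s1", support = list("A")) {
  df <- data.frame(locus_id = sprintf("uce-%d", seq_along(starts)),
                   scaffold = scaffold, start = starts, end = ends,
                   stringsAsFactors = FALSE)
  df$support <- rep(support, length.out = nrow(df))
  uceforge:::new_locus_table(df, exemplars = unique(unlist(support)))
}

test_that("extraction takes a centered window of min(extract_len, locus length)", {
  g <- random_genome(2000, seed = 51)
  tab <- make_table(c(100, 700), c(500, 850))  # lengths 400 and 150
  reg <- extract_design_regions(tab, g)
  expect_equal(reg$end - reg$start, c(160L, 150L))
  expect_equal(reg$start[1], 100 + (400 - 160) %/% 2)   # centered
  expect_equal(reg$start[2], 700L)                      # whole locus
  expect_equal(reg$sequence,
               get_sequence(g, reg$scaffold, reg$start, reg$end))
  # left bias: odd centering puts the extra base on the right
  tab2 <- make_table(100, 261)  # length 161
  reg2 <- extract_design_regions(tab2, g)
  expect_equal(c(reg2$start, reg2$end), c(100L, 260L))
})

test_that("extraction windows are re-filtered by the strip rules", {
  s <- random_dna(1000, seed = 52)
  s <- paste0(substr(s, 1, 460), "N", substr(s, 462, 1000))
  g <- genome_assembly(c(s1 = s), "t")
  tab <- make_table(c(300, 700), c(620, 900))  # first window spans the N
  reg <- extract_design_regions(tab, g)
  expect_equal(reg$locus_id, "uce-2")
})

test_that("tiling uses a 40-bp step plus an anchored final probe", {
  mk <- function(L) data.frame(locus_id = "uce-1", taxon = "t",
                               scaffold = "s1", start = 0L, end = L,
                               sequence = random_dna(L, seed = L),
                               stringsAsFactors = FALSE)
  starts_of <- function(L) tile_probes(mk(L))$start
  expect_equal(starts_of(160), c(0L, 40L))
  expect_equal(starts_of(120), 0L)
  expect_equal(starts_of(190), c(0L, 40L, 70L))
  expect_equal(starts_of(180), c(0L, 40L, 60L))
  p <- tile_probes(mk(160))
  expect_equal(p$tile_index, 0:1)
  expect_equal(unique(nchar(p$sequence)), 120L)
  expect_true(all(p$sequence == toupper(p$sequence)))
  # each probe extends 40 bases past the locus middle (position 80)
  expect_equal(p$end[1] - 80L, 40L)
  expect_equal(80L - p$start[2], 40L)
  expect_error(tile_probes(mk(160), probe_len = 120, density = 7),
               class = "uceforge_parameter_error")
  expect_warning(tile_probes(mk(100)), "shorter")
})

test_that("GC screen boundaries are inclusive at 30 % and 70 %", {
  gc_probe <- function(n_gc) paste0(strrep("G", n_gc), strrep("A", 120 - n_gc))
  scr <- screen_probes(probe_frame(vapply(c(84, 85, 36, 35, 0), gc_probe, ""),
                                   locus_id = sprintf("L%d", 1:5)))
  expect_equal(scr$kept$locus_id, c("L1", "L3"))    # 70.0 % and 30.0 % kept
  expect_equal(scr$dropped$reason, rep("gc", 3))    # 70.83 %, 29.17 %, 0 %
})

test_that("mask and ambiguity screens use the probe's pre-uppercase source", {
  seqs <- strrep("GA", 60)
  probes <- probe_frame(rep(seqs, 3), locus_id = c("L1", "L2", "L3"),
                        masked = c(31L, 30L, 0L))
  probes$ambiguous[3] <- TRUE
  scr <- screen_probes(probes)
  expect_equal(scr$kept$locus_id, "L2")              # 25.83 % masked dropped
  expect_setequal(scr$dropped$reason, c("masked", "ambiguous"))
})

test_that("screen order does not matter (GC and mask filters commute)", {
  uceforge:::with_seed(53, {
    seqs <- vapply(1:30, function(i) random_dna(120), "")
    probes <- probe_frame(seqs, locus_id = sprintf("L%d", 1:30),
                          masked = sample(0:40, 30, TRUE))
    a <- screen_probes(probes, gc_min = 0.4, gc_max = 0.6, mask_max = 0.25)
    b <- screen_probes(
      screen_probes(probes, gc_min = 0, gc_max = 1, mask_max = 0.25)$kept,
      gc_min = 0.4, gc_max = 0.6, mask_max = 1)
    expect_equal(a$kept$sequence, b$kept$sequence)
  })
})

test_that("duplicate loci are removed pairwise; random loci survive", {
  shared <- random_dna(120, seed = 54)
  probes <- probe_frame(
    c(shared, shared, random_dna(120, seed = 55), random_dna(120, seed = 56)),
    locus_id = c("A", "B", "C", "D"))
  kept <- remove_duplicate_loci(probes)
  expect_setequal(unique(kept$locus_id), c("C", "D"))
  expect_setequal(attr(kept, "removed_loci"), c("A", "B"))
})

test_that("duplicate screen agrees with a brute-force local-alignment oracle", {
  uceforge:::with_seed(57, {
    base <- vapply(1:8, function(i) random_dna(120), "")
    # loci 1/2 near-identical, 3/4 share a revcomp copy, rest independent
    seqs <- base
    seqs[2] <- mutate_seq(base[1], sample(120, 6))
    seqs[4] <- revcomp(base[3])
    probes <- probe_frame(seqs, locus_id = sprintf("L%d", 1:8))
    kept <- remove_duplicate_loci(probes)

    # oracle: exhaustive all-pairs Smith-Waterman, no prefilter
    mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
    flag <- character()
    for (i in 1:7) for (j in (i + 1):8) {
      hit <- FALSE
      for (b in c(seqs[j], revcomp(seqs[j]))) {
        pa <- Biostrings::pairwiseAlignment(toupper(seqs[i]), toupper(b),
                                            type = "local",
                                            substitutionMatrix = mat,
                                            gapOpening = 5, gapExtension = 2)
        alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
        cov <- IRanges::width(pa@pattern@range)
        if (alen > 0 && Biostrings::nmatch(pa) / alen >= 0.5 && cov >= 60)
          hit <- TRUE
      }
      if (hit) flag <- union(flag, sprintf("L%d", c(i, j)))
    }
    expect_setequal(attr(kept, "removed_loci"), flag)
    expect_true(all(c("L1", "L2", "L3", "L4") %in% flag))
  })
})

test_that("align-back recovers source coordinates and buffers slices to 180 bp", {
  g <- random_genome(3000, seed = 58, taxon = "base")
  probe <- get_sequence(g, "s1", 1000, 1120)
  probes <- probe_frame(probe, locus_id = "uce-1", taxon = "base")
  slices <- alignback_and_slice(probes, list(base = g))
  expect_equal(nrow(slices), 1L)
  expect_equal(c(slices$start, slices$end), c(970L, 1150L))  # 120 -> 180
  expect_equal(nchar(slices$sequence), 180L)
  expect_false(slices$clipped)
  expect_equal(slices$sequence, get_sequence(g, "s1", 970, 1150))
})

test_that("align-back removes loci whose probes hit multiple regions", {
  core <- random_dna(120, seed = 59)
  g <- genome_assembly(
    c(s1 = paste0(random_dna(400, seed = 60), core,
                  random_dna(400, seed = 61), core,
                  random_dna(400, seed = 62))), "t")
  uniq <- get_sequence(g, "s1", 100, 220)
  probes <- probe_frame(c(core, uniq), locus_id = c("dup", "ok"), taxon = "t")
  slices <- alignback_and_slice(probes, list(t = g))
  expect_equal(attr(slices, "removed_loci"), "dup")
  expect_equal(unique(slices$locus_id), "ok")
})

test_that("slices at scaffold edges are kept at reduced length and flagged", {
  g <- random_genome(500, seed = 63)
  probe <- get_sequence(g, "s1", 0, 120)
  slices <- alignback_and_slice(probe_frame(probe, "uce-1", taxon = "t"),
                                list(t = g))
  expect_true(slices$clipped)
  expect_equal(slices$start, 0L)
  expect_lt(nchar(slices$sequence), 180L)
})

test_that("final set tiles every taxon's slice, collapses exact duplicates", {
  uceforge:::with_seed(64, {
    taxa <- sprintf("t%d", 1:5)
    base_slice <- random_dna(180)
    slices <- data.frame(
      locus_id = "uce-1", taxon = taxa, scaffold = "s1", start = 0L,
      end = 180L,
      sequence = c(base_slice,
                   vapply(2:5, function(i)
                     mutate_seq(base_slice, sample(180, 9)), "")),
      clipped = FALSE, stringsAsFactors = FALSE)
    final <- design_final_set(slices, min_exemplars = 5)
    expect_equal(nrow(final), 15L)  # 3 tiles x 5 taxa, no exact duplicates
    dup <- slices
    dup$sequence <- base_slice     # identical slices collapse
    expect_equal(nrow(design_final_set(dup, 5)), 3L)
    expect_error(design_final_set(slices, 6),
                 class = "uceforge_parameter_error")
    # a locus supported by fewer taxa than min_exemplars contributes nothing
    weak <- slices[1:3, ]; weak$locus_id <- "uce-2"
    mix <- design_final_set(rbind(slices, weak), 4)
    expect_equal(unique(mix$locus_id), "uce-1")
  })
})

test_that("per-locus probe count is bounded by taxa x tiles and >= 1", {
  fx <- clade_fixture()
  probes <- fx$des5$probes
  per_locus <- table(probes$locus_id)
  expect_true(all(per_locus >= 1))
  expect_true(all(per_locus <= 6 * 3))
  expect_false(any(duplicated(probes$sequence)))
})
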