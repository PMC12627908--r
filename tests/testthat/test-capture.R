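# In-silico capture: flank slicing geometry, the one-to-one duplicate screen,
# and the LE/LR/LRT accounting.

# one genome with two well-separated planted probe targets
capture_fixture <- function(seed = 71) {
  uceforge:::with_seed(seed, {
    l1 <- random_dna(180); l2 <- random_dna(180)
    g <- genome_assembly(
      c(s1 = paste0(random_dna(1500), l1, random_dna(1500), l2,
                    random_dna(1500))), "tx")
    probes <- rbind(
      probe_frame(c(substr(l1, 1, 120), substr(l1, 61, 180)), "uce-1",
                  taxon = "tx", tile_index = 0:1),
      probe_frame(c(substr(l2, 1, 120), substr(l2, 61, 180)), "uce-2",
                  taxon = "tx", tile_index = 0:1))
    list(genome = g, probes = uceforge:::new_probe_set(probes),
         l1_start = 1500L, l2_start = 1500L + 180L + 1500L)
  })
}

test_that("self-capture recovers source loci at identity 1 with 400-bp flanks", {
  fx <- capture_fixture()
  caps <- capture(fx$probes, fx$genome)
  expect_equal(nrow(caps), 2L)
  expect_equal(caps$identity, c(1, 1))
  expect_equal(caps$matched_len, c(180L, 180L))
  expect_equal(caps$start, c(fx$l1_start - 400L, fx$l2_start - 400L))
  expect_equal(nchar(caps$sequence), c(980L, 980L))  # 180 + 2 x 400
  expect_equal(caps$sequence[1],
               get_sequence(fx$genome, "s1", caps$start[1], caps$end[1]))
})

test_that("flanks are clipped at scaffold bounds", {
  uceforge:::with_seed(72, {
    locus <- random_dna(120)
    g <- genome_assembly(c(s1 = paste0(random_dna(100), locus,
                                       random_dna(2000))), "tx")
    caps <- capture(probe_frame(locus, "uce-1", taxon = "tx"), g)
    expect_equal(caps$start, 0L)           # left flank clipped 400 -> 100
    expect_equal(caps$end, 100L + 120L + 400L)
  })
})

test_that("the 80/80 screen keeps clean one-to-one captures and drops collisions", {
  fx <- capture_fixture()
  caps <- capture(fx$probes, fx$genome)
  dd <- dedupe_captures(caps, fx$probes)
  expect_equal(nrow(dd$kept), 2L)
  expect_equal(nrow(dd$removed), 0L)

  # a capture matching probes of two loci above threshold is removed
  chimera <- caps[1, ]
  chimera$sequence <- paste0(caps$sequence[1], caps$sequence[2])
  dd2 <- dedupe_captures(rbind(caps[2, ], chimera), fx$probes)
  expect_equal(dd2$removed$reason, "multi_locus")

  # two captures of one locus in one taxon are both removed
  twin <- caps[c(1, 1, 2), ]
  dd3 <- dedupe_captures(twin, fx$probes)
  expect_equal(sort(dd3$removed$reason), rep("locus_collision", 2))
  expect_equal(dd3$kept$locus_id, "uce-2")
})

test_that("capture identity below the screen threshold is removed", {
  fx <- capture_fixture()
  caps <- capture(fx$probes, fx$genome)
  # mutate every 3rd base of the first captured locus, sparing a 20-bp
  # island so seeding still succeeds: every >= 80 %-coverage window of any
  # probe then has identity well under 80 %
  pos <- 400 + setdiff(seq(1, 180, by = 3), 81:100)
  caps$sequence[1] <- mutate_seq(caps$sequence[1], pos)
  dd <- dedupe_captures(caps, fx$probes, min_identity = 0.80,
                        min_coverage = 0.80)
  expect_true("uce-1" %in% dd$removed$locus_id)
  expect_equal(dd$kept$locus_id, "uce-2")
})

test_that("kept and removed partition the input; thresholds validated", {
  fx <- capture_fixture()
  caps <- capture(fx$probes, fx$genome)
  dd <- dedupe_captures(caps, fx$probes)
  expect_equal(nrow(dd$kept) + nrow(dd$removed), nrow(caps))
  expect_error(dedupe_captures(caps, fx$probes, min_identity = 1.2),
               class = "uceforge_parameter_error")
  expect_error(dedupe_captures(caps, fx$probes, min_coverage = 0),
               class = "uceforge_parameter_error")
})

test_that("lowering min_identity never decreases the kept count", {
  fx <- clade_fixture()
  caps <- rbind(capture(fx$des5$probes, fx$clade$genomes$t1),
                capture(fx$des5$probes, fx$clade$genomes$t4))
  kept_n <- vapply(c(0.95, 0.80, 0.60), function(thr)
    nrow(dedupe_captures(caps, fx$des5$probes, min_identity = thr,
                         min_coverage = 0.8)$kept), 0L)
  expect_true(all(diff(kept_n) >= 0))
})

test_that("capture counts report LE / LR / LRT per taxon", {
  kept <- data.frame(locus_id = sprintf("uce-%d", 1:8), taxon = "t1")
  removed <- data.frame(locus_id = c("uce-9", "uce-10"), taxon = "t1",
                        reason = "multi_locus")
  cc <- capture_counts(kept, removed)
  expect_equal(cc$loci_extracted, 10L)
  expect_equal(cc$loci_removed, 2L)
  expect_equal(cc$loci_retained, 8L)
  empty <- capture_counts(kept[0, ], removed[0, ])
  expect_equal(nrow(empty), 0L)
  # permutation invariance
  cc2 <- capture_counts(kept[sample(8), ], removed[2:1, ])
  expect_equal(cc2, cc)
})
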