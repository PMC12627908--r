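# Locus-matrix statistics: completeness, concatenation, informative sites,
# p/K80 distances (with ape as the independent oracle), SNPs and PCA.

aln <- function(...) {
  x <- c(...)
  setNames(as.character(x), names(x))
}

test_that("completeness filter keeps loci present in >= ceil(frac * taxa)", {
  taxa <- sprintf("t%02d", 1:10)
  mk <- function(k) setNames(rep("ACGT", k), taxa[seq_len(k)])
  m <- locus_matrix(list(l7 = mk(7), l6 = mk(6), l10 = mk(10)), taxa = taxa)
  f <- completeness_filter(m, 0.70)
  expect_setequal(f$loci, c("l7", "l10"))
  expect_setequal(completeness_filter(m, 0.001)$loci, c("l7", "l6", "l10"))
  expect_error(completeness_filter(m, 0), class = "uceforge_parameter_error")
  expect_error(completeness_filter(m, 1.1), class = "uceforge_parameter_error")
})

test_that("concatenation fills absences with ? and partitions are 1-based", {
  m <- locus_matrix(list(
    a = aln(t1 = strrep("A", 100), t2 = strrep("C", 100)),
    b = aln(t1 = strrep("G", 50))
  ), taxa = c("t1", "t2"))
  cc <- concatenate_matrix(m)
  expect_equal(nchar(cc$supermatrix[["t1"]]), 150L)
  expect_equal(cc$partitions$start, c(1L, 101L))
  expect_equal(cc$partitions$end, c(100L, 150L))
  expect_equal(substring(cc$supermatrix[["t2"]], 101, 150), strrep("?", 50))
  # per-partition extraction is the identity
  expect_equal(substring(cc$supermatrix[["t1"]], 101, 150), strrep("G", 50))
})

test_that("parsimony-informative definition: two states in two taxa each", {
  col <- function(x) {
    m <- locus_matrix(list(l = setNames(x, sprintf("t%d", seq_along(x)))))
    count_informative_sites(m)
  }
  expect_equal(col(c("A", "A", "T", "T")), 1L)
  expect_equal(col(c("A", "A", "A", "T")), 0L)
  expect_equal(col(c("A", "A", "-", "T", "?")), 0L)
  expect_equal(col(c("A", "A", "N", "T", "T")), 1L)
})

test_that("informative-site counts match an exhaustive per-column oracle", {
  oracle <- function(m) {
    total <- 0L
    for (lid in m$loci) {
      a <- m$alignments[[lid]]
      chars <- do.call(rbind, strsplit(toupper(a), ""))
      for (j in seq_len(ncol(chars))) {
        tab <- table(chars[, j])
        tab <- tab[names(tab) %in% c("A", "C", "G", "T")]
        if (sum(tab >= 2) >= 2) total <- total + 1L
      }
    }
    total
  }
  uceforge:::with_seed(81, {
    for (rep in 1:25) {
      seqs <- vapply(1:10, function(i)
        paste(sample(c("A", "C", "G", "T", "-", "?", "N"), 120, TRUE,
                     prob = c(rep(0.22, 4), 0.05, 0.04, 0.03)),
              collapse = ""), "")
      m <- locus_matrix(list(l = setNames(seqs, sprintf("t%d", 1:10))))
      expect_equal(count_informative_sites(m), oracle(m))
    }
  })
})

test_that("closed-form distances: 100 transitions over 1000 sites", {
  s1 <- strrep("A", 500)
  s2 <- paste0(strrep("G", 100), strrep("A", 400))  # 100 A->G transitions
  m <- locus_matrix(list(l = aln(t1 = paste0(s1, strrep("C", 500)),
                                 t2 = paste0(s2, strrep("C", 500)))))
  p <- pairwise_distances(m, "p")
  k <- pairwise_distances(m, "K80")
  expect_equal(p["t1", "t2"], 0.100, tolerance = 1e-14)
  expect_lt(abs(k["t1", "t2"] - (-0.5 * log(0.8))), 1e-12)
  expect_equal(diag(p), c(t1 = 0, t2 = 0))
  ident <- locus_matrix(list(l = aln(t1 = "ACGT", t2 = "ACGT")))
  expect_equal(pairwise_distances(ident, "K80")["t1", "t2"], 0)
})

test_that("pairwise deletion drops sites with gaps or ambiguity in either taxon", {
  m <- locus_matrix(list(l = aln(t1 = "ACGTAC-TN?",
                                 t2 = "ACGAAC-T-A")))
  # valid columns: 1..6, 8 (7 is gap/gap, 9-10 ambiguous/gap); one mismatch
  p <- pairwise_distances(m, "p")
  expect_equal(p["t1", "t2"], 1 / 7)
})

test_that("K80 >= p and both match ape::dist.dna on random alignments", {
  uceforge:::with_seed(82, {
    for (rep in 1:5) {
      n <- 6
      anc <- sample(c("a", "c", "g", "t"), 800, TRUE)
      seqs <- vapply(1:n, function(i) {
        x <- anc
        idx <- sample(800, 160)
        x[idx] <- sample(c("a", "c", "g", "t"), 160, TRUE)
        paste(x, collapse = "")
      }, "")
      m <- locus_matrix(list(l = setNames(toupper(seqs),
                                          sprintf("t%d", 1:n))))
      p <- pairwise_distances(m, "p")
      k <- suppressWarnings(pairwise_distances(m, "K80"))
      expect_true(all(k >= p - 1e-12, na.rm = TRUE))
      bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
      rownames(bin) <- sprintf("t%d", 1:n)
      expect_equal(unclass(ape::dist.dna(bin, "raw", pairwise.deletion = TRUE)),
                   unclass(as.dist(p)), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(unclass(ape::dist.dna(bin, "K80", pairwise.deletion = TRUE)),
                   unclass(as.dist(k)), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  })
})

test_that("saturated pairs yield NA with a warning", {
  m <- locus_matrix(list(l = aln(t1 = strrep("AC", 50),
                                 t2 = strrep("GT", 50))))
  expect_warning(k <- pairwise_distances(m, "K80"), "saturated")
  expect_true(is.na(k["t1", "t2"]))
})

test_that("SNP extraction keeps only biallelic sites under the missing cap", {
  taxa <- sprintf("t%d", 1:10)
  col_aln <- function(chars) locus_matrix(
    list(l = setNames(chars, taxa)), taxa = taxa)
  # three alleles -> excluded
  expect_equal(ncol(extract_snps(col_aln(c("A","A","A","C","C","G","G","A","A","A")))$genotypes), 0L)
  # invariant -> excluded
  expect_equal(ncol(extract_snps(col_aln(rep("A", 10)))$genotypes), 0L)
  # biallelic, 30 % missing at max 0.25 -> excluded
  expect_equal(ncol(extract_snps(col_aln(c("A","A","A","A","C","C","C","N","N","-")))$genotypes), 0L)
  # biallelic, 20 % missing -> retained; major allele coded 0
  snp <- extract_snps(col_aln(c("A","A","A","A","C","C","C","A","N","-")))
  expect_equal(ncol(snp$genotypes), 1L)
  expect_equal(unname(snp$genotypes[, 1]),
               c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L, NA, NA))
  # tie between alleles: alphabetically first base becomes 0
  snp2 <- extract_snps(col_aln(c("T","T","T","T","T","G","G","G","G","G")))
  expect_equal(unname(snp2$genotypes[, 1]),
               c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("extracted SNPs are always biallelic with missingness below the cap", {
  uceforge:::with_seed(83, {
    for (rep in 1:10) {
      taxa <- sprintf("t%d", 1:8)
      seqs <- vapply(1:8, function(i)
        paste(sample(c("A", "C", "G", "T", "N", "-"), 200, TRUE,
                     prob = c(0.4, 0.25, 0.15, 0.1, 0.05, 0.05)),
              collapse = ""), "")
      m <- locus_matrix(list(l = setNames(seqs, taxa)))
      snp <- extract_snps(m, max_missing = 0.25)
      if (ncol(snp$genotypes) == 0) next
      for (j in seq_len(ncol(snp$genotypes))) {
        g <- snp$genotypes[, j]
        expect_lt(mean(is.na(g)), 0.25)
        expect_setequal(unique(stats::na.omit(g)), c(0L, 1L))
      }
    }
  })
})

test_that("PCA separates two fixed-allele groups on PC1 and centers scores", {
  taxa <- sprintf("t%d", 1:10)
  G <- cbind(matrix(rep(c(0L, 1L), each = 5), nrow = 10, ncol = 100))
  snps <- structure(list(taxa = taxa,
                         sites = data.frame(locus_id = "l",
                                            column = 1:100),
                         genotypes = `dimnames<-`(G, list(taxa, NULL))),
                    class = "snp_matrix")
  sc <- snp_pca(snps, 2)
  expect_true(all(sc[1:5, 1] * sc[6:10, 1] < 0))   # opposite signs by group
  expect_lt(max(abs(colSums(sc))), 1e-8)
  # degenerate inputs: identical genotypes -> all-zero scores
  G0 <- matrix(1L, 4, 10, dimnames = list(sprintf("t%d", 1:4), NULL))
  snps0 <- structure(list(taxa = rownames(G0), sites = NULL, genotypes = G0),
                     class = "snp_matrix")
  expect_warning(sc0 <- snp_pca(snps0, 5), "clipped")
  expect_true(all(abs(sc0) < 1e-10))
})

test_that("PHYLIP, partition and TSV writers emit the expected shapes", {
  m <- locus_matrix(list(
    `uce-1` = aln(t1 = strrep("A", 30), t2 = strrep("C", 30)),
    `uce-2` = aln(t1 = strrep("G", 20), t2 = strrep("T", 20))))
  cc <- concatenate_matrix(m)
  phy <- tempfile(); write_supermatrix_phylip(cc$supermatrix, phy)
  lines <- readLines(phy)
  expect_equal(lines[1], "2 50")
  part <- tempfile(); write_partitions(cc$partitions, part)
  expect_equal(readLines(part),
               c("DNA, uce-1 = 1-30", "DNA, uce-2 = 31-50"))
  d <- pairwise_distances(m, "p")
  tsv <- tempfile(); write_matrix_tsv(d, tsv)
  expect_equal(nrow(read.table(tsv, header = TRUE, sep = "\t")), 2L)
})
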