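# Locus-matrix assembly and downstream statistics: completeness filtering,
# supermatrix concatenation, parsimony-informative sites, uncorrected p and
# Kimura 1980 distances with pairwise deletion, binary SNP extraction, PCA.

#' Construct a locus matrix
#'
#' A locus matrix holds per-locus alignments (gap `-`, missing `?`/`N`
#' allowed) over a common taxon set. Within a locus all sequences must have
#' equal length.
#'
#' @param alignments named list: locus_id -> named character vector
#'   (taxon -> aligned sequence).
#' @param taxa optional ordered taxon labels; defaults to the union in order
#'   of first appearance.
#' @return an object of class `locus_matrix`.
#' @export
locus_matrix <- function(alignments, taxa = NULL) {
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    parameter_error("alignments must be a named list (locus ids)")
  for (lid in names(alignments)) {
    aln <- alignments[[lid]]
    if (is.null(names(aln)) || any(names(aln) == ""))
      parameter_error(sprintf("locus %s: sequences must be named by taxon", lid))
    if (length(unique(nchar(aln))) > 1L)
      format_error(sprintf("locus %s: unequal sequence lengths", lid))
  }
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(alignments, names), use.names = FALSE))
  structure(list(taxa = taxa, loci = names(alignments),
                 alignments = alignments),
            class = "locus_matrix")
}

#' @export
print.locus_matrix <- function(x, ...) {
  cat(sprintf("<locus_matrix> %d loci x %d taxa, %s aligned columns\n",
              length(x$loci), length(x$taxa),
              format(sum(vapply(x$alignments, function(a)
                nchar(a[[1]]), 0)), big.mark = ",")))
  invisible(x)
}

#' Read per-locus alignments from a directory or monolithic FASTA
#'
#' A directory is scanned for `*.fasta`/`*.fa` files (one locus each, record
#' names are taxa); a single file is parsed with the monolithic locus header
#' convention of [write_monolithic_locus_fasta()].
#'
#' @param path directory of per-locus FASTA files, or one monolithic file.
#' @return a [locus_matrix()].
#' @export
read_locus_alignments <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (length(files) == 0L) format_error(sprintf("%s: no FASTA files", path))
    alignments <- lapply(files, function(f) {
      set <- Biostrings::readBStringSet(f)
      setNames(as.character(set), sub("\\s.*$", "", names(set)))
    })
    names(alignments) <- sub("\\.(fa|fasta)$", "", basename(files))
    locus_matrix(alignments)
  } else {
    df <- read_monolithic_locus_fasta(path)
    alignments <- lapply(split(df, df$locus_id), function(d)
      setNames(d$sequence, d$taxon))
    locus_matrix(alignments)
  }
}

#' Build a locus matrix from captured loci (indel-free data only)
#'
#' Groups captured sequences by locus; within a locus, sequences shorter than
#' the longest (flank clipping at scaffold edges) are right-padded with `?`.
#' Valid only when the captures are co-linear (no indels), as for the
#' synthetic clades this package generates; real captures must be aligned
#' externally first.
#'
#' @param captures a `captured_loci` frame.
#' @param taxa optional ordered taxon labels.
#' @return a [locus_matrix()].
#' @export
captures_to_locus_matrix <- function(captures, taxa = NULL) {
  if (is.null(taxa)) taxa <- unique(captures$taxon)
  alignments <- lapply(split(captures, captures$locus_id), function(d) {
    d <- d[!duplicated(d$taxon), , drop = FALSE]
    w <- max(nchar(d$sequence))
    pad <- strrep("?", w - nchar(d$sequence))
    setNames(toupper(paste0(d$sequence, pad)), d$taxon)
  })
  locus_matrix(alignments, taxa = taxa)
}

#' Keep loci present in at least a fraction of taxa
#'
#' A locus is kept iff it has a non-empty sequence in at least
#' `ceil(min_fraction * n_taxa)` taxa. `min_fraction` near 0 behaves as the
#' incomplete matrix (all loci).
#'
#' @param matrix a [locus_matrix()].
#' @param min_fraction completeness fraction in (0, 1].
#' @return the filtered [locus_matrix()].
#' @export
completeness_filter <- function(matrix, min_fraction) {
  if (min_fraction <= 0 || min_fraction > 1)
    parameter_error("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * length(matrix$taxa))
  present <- vapply(matrix$alignments, function(a)
    sum(names(a) %in% matrix$taxa & nchar(a) > 0L), 0L)
  locus_matrix(matrix$alignments[present >= need], taxa = matrix$taxa)
}

#' Concatenate a locus matrix into a supermatrix with partitions
#'
#' Loci are concatenated in locus order; absent taxon-by-locus blocks are
#' filled with `?`. The partition table uses 1-based inclusive coordinates
#' (the convention of phylogenetic partition files).
#'
#' @param matrix a [locus_matrix()].
#' @return list with `supermatrix` (named character vector, taxon ->
#'   concatenated sequence) and `partitions` (data frame `locus_id`, `start`,
#'   `end`, 1-based inclusive).
#' @export
concatenate_matrix <- function(matrix) {
  if (length(matrix$loci) == 0L) parameter_error("matrix has no loci")
  lens <- vapply(matrix$alignments, function(a) nchar(a[[1]]), 0L)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- vapply(matrix$taxa, function(tx) {
    paste(vapply(seq_along(matrix$loci), function(i) {
      a <- matrix$alignments[[i]]
      if (tx %in% names(a) && nchar(a[[tx]]) > 0L) a[[tx]]
      else strrep("?", lens[i])
    }, ""), collapse = "")
  }, "")
  list(supermatrix = setNames(blocks, matrix$taxa),
       partitions = data.frame(locus_id = matrix$loci,
                               start = as.integer(starts),
                               end = as.integer(ends),
                               stringsAsFactors = FALSE))
}

# character matrix (taxa x columns) for one locus, uppercase
.locus_char_matrix <- function(matrix, lid) {
  a <- matrix$alignments[[lid]]
  a <- a[nchar(a) > 0L]
  if (length(a) == 0L) return(NULL)
  w <- nchar(a[[1]])
  m <- matrix(NA_integer_, nrow = length(a), ncol = w)
  for (i in seq_along(a)) m[i, ] <- utf8ToInt(toupper(a[[i]]))
  m
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative iff at least two distinct unambiguous
#' bases (A/C/G/T) each occur in at least two taxa; gaps and ambiguities are
#' excluded from state counts. Returns the count over all loci.
#'
#' @param matrix a [locus_matrix()].
#' @return integer count.
#' @export
count_informative_sites <- function(matrix) {
  codes <- utf8ToInt("ACGT")
  total <- 0L
  for (lid in matrix$loci) {
    m <- .locus_char_matrix(matrix, lid)
    if (is.null(m)) next
    counts <- vapply(codes, function(cd) colSums(m == cd),
                     numeric(ncol(m)))
    if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
    total <- total + sum(rowSums(counts >= 2L) >= 2L)
  }
  total
}

#' Pairwise distances under uncorrected p or Kimura 1980
#'
#' Sites where either sequence is a gap or ambiguous are deleted per pair
#' (pairwise deletion). `p` is the fraction of mismatching valid sites. `K80`
#' corrects using the transition fraction P (A<->G, C<->T) and transversion
#' fraction Q: `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Saturated pairs
#' (log argument <= 0) and pairs with no valid sites yield `NA` with a
#' warning.
#'
#' @param matrix a [locus_matrix()].
#' @param model `"p"` or `"K80"`.
#' @return symmetric taxa-by-taxa numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(matrix, model = c("p", "K80")) {
  model <- match.arg(model)
  taxa <- matrix$taxa
  if (length(taxa) < 2L) parameter_error("need at least two taxa")
  conc <- concatenate_matrix(matrix)$supermatrix[taxa]
  enc <- lapply(conc, function(s) utf8ToInt(toupper(s)))
  valid <- lapply(enc, function(v) .acgt_codes[v])
  transition_partner <- local({
    v <- integer(256)
    v[utf8ToInt("A")] <- utf8ToInt("G"); v[utf8ToInt("G")] <- utf8ToInt("A")
    v[utf8ToInt("C")] <- utf8ToInt("T"); v[utf8ToInt("T")] <- utf8ToInt("C")
    v
  })
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[[i]] & valid[[j]]
    nv <- sum(ok)
    if (nv == 0L) { D[i, j] <- D[j, i] <- NA_real_; saturated <- TRUE; next }
    a <- enc[[i]][ok]; b <- enc[[j]][ok]
    diff <- a != b
    if (model == "p") {
      d <- sum(diff) / nv
    } else {
      ts <- sum(diff & (transition_partner[a] == b))
      tv <- sum(diff) - ts
      P <- ts / nv; Q <- tv / nv
      arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
      if (arg1 <= 0 || arg2 <= 0) { d <- NA_real_; saturated <- TRUE }
      else d <- -0.5 * log(arg1) - 0.25 * log(arg2)
    }
    D[i, j] <- D[j, i] <- d
  }
  if (saturated)
    warning("some pairs are saturated or share no valid sites: NA distances",
            call. = FALSE)
  D
}

#' Extract binary SNPs from a locus matrix
#'
#' Per column, taxa with gap/`N`/ambiguity are missing; the site is retained
#' iff exactly two distinct bases occur among non-missing taxa AND the missing
#' fraction is strictly below `max_missing`. The major allele (ties broken by
#' alphabetical order) is encoded 0, the minor allele 1.
#'
#' @param matrix a [locus_matrix()].
#' @param max_missing maximum missing fraction, exclusive (default 0.25).
#' @return object of class `snp_matrix`: list with `taxa`, `sites` (data frame
#'   `locus_id`, `column` 1-based) and `genotypes` (taxa x sites matrix of
#'   0/1/NA).
#' @export
extract_snps <- function(matrix, max_missing = 0.25) {
  taxa <- matrix$taxa
  n <- length(taxa)
  codes <- utf8ToInt("ACGT")
  geno <- list(); sites <- list()
  for (lid in matrix$loci) {
    a <- matrix$alignments[[lid]]
    w <- nchar(a[[1]])
    m <- matrix(NA_integer_, nrow = n, ncol = w)
    for (i in seq_len(n)) {
      tx <- taxa[i]
      if (tx %in% names(a) && nchar(a[[tx]]) > 0L)
        m[i, ] <- utf8ToInt(toupper(a[[tx]]))
    }
    m[!is.na(m) & !matrix(.acgt_codes[m], nrow = n)] <- NA_integer_
    counts <- vapply(codes, function(cd) colSums(m == cd, na.rm = TRUE),
                     numeric(w))
    if (w == 1L) counts <- matrix(counts, nrow = 1L)
    nmiss <- colSums(is.na(m))
    nalleles <- rowSums(counts > 0L)
    keep <- which(nalleles == 2L & nmiss / n < max_missing)
    for (col in keep) {
      cc <- counts[col, ]
      alleles <- codes[cc > 0L]
      # major allele = most frequent, ties -> alphabetically first base
      major <- alleles[order(-cc[cc > 0L], alleles)][1]
      g <- ifelse(is.na(m[, col]), NA_integer_,
                  ifelse(m[, col] == major, 0L, 1L))
      geno[[length(geno) + 1L]] <- g
      sites[[length(sites) + 1L]] <- data.frame(
        locus_id = lid, column = col, stringsAsFactors = FALSE)
    }
  }
  if (length(geno) == 0L) {
    G <- matrix(integer(), nrow = n, ncol = 0L,
                dimnames = list(taxa, NULL))
    sdf <- data.frame(locus_id = character(), column = integer(),
                      stringsAsFactors = FALSE)
  } else {
    G <- do.call(cbind, geno)
    dimnames(G) <- list(taxa, NULL)
    sdf <- do.call(rbind, sites)
  }
  structure(list(taxa = taxa, sites = sdf, genotypes = G),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d taxa x %d biallelic sites\n",
              length(x$taxa), ncol(x$genotypes)))
  invisible(x)
}

#' Principal component analysis of a SNP matrix
#'
#' Missing genotypes are mean-imputed per site, the matrix is column-centered,
#' and scores are the projections onto the top right-singular directions.
#' Component signs are unspecified. `n_components` larger than
#' `min(taxa - 1, sites)` is clipped with a warning.
#'
#' @param snps a `snp_matrix`.
#' @param n_components number of components (default 2).
#' @return taxa-by-components score matrix of class `snp_pca_scores`, with the
#'   singular values in attribute `sdev`.
#' @export
snp_pca <- function(snps, n_components = 2L) {
  G <- snps$genotypes
  if (nrow(G) < 2L || ncol(G) < 1L)
    parameter_error("need at least 2 taxa and 1 site")
  for (j in seq_len(ncol(G))) {
    mu <- mean(G[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    G[is.na(G[, j]), j] <- mu
  }
  X <- scale(G, center = TRUE, scale = FALSE)
  kmax <- min(nrow(G) - 1L, ncol(G))
  if (n_components > kmax) {
    warning(sprintf("n_components clipped to %d", kmax), call. = FALSE)
    n_components <- kmax
  }
  sv <- svd(X, nu = 0, nv = n_components)
  scores <- X %*% sv$v
  dimnames(scores) <- list(snps$taxa, paste0("PC", seq_len(n_components)))
  structure(scores, sdev = sv$d / sqrt(max(1, nrow(G) - 1L)),
            class = c("snp_pca_scores", class(scores)))
}

#' @export
plot.snp_pca_scores <- function(x, ...) {
  graphics::plot(x[, 1], if (ncol(x) > 1) x[, 2] else rep(0, nrow(x)),
                 xlab = "PC1", ylab = if (ncol(x) > 1) "PC2" else "",
                 pch = 19, ...)
  graphics::text(x[, 1], if (ncol(x) > 1) x[, 2] else rep(0, nrow(x)),
                 labels = rownames(x), pos = 3, cex = 0.7)
  invisible(x)
}

# --- writers ----------------------------------------------------------------

#' Write a supermatrix as relaxed PHYLIP
#'
#' @param supermatrix named character vector (taxon -> sequence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_supermatrix_phylip <- function(supermatrix, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(supermatrix),
                     nchar(supermatrix[[1]])), con)
  writeLines(sprintf("%s  %s", names(supermatrix), supermatrix), con)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One `DNA, <locus> = <start>-<end>` line per locus (1-based inclusive).
#'
#' @param partitions partition data frame from [concatenate_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$locus_id,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' Write a distance matrix / SNP matrix / PCA scores as TSV
#'
#' @param x matrix-like object with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
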