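# Error-free paired-end read simulation from exemplar genomes (the in-silico
# ART step). Fragments start uniformly along each scaffold; fragment lengths
# are normal(frag_mean, frag_sd) truncated to [read_len, scaffold length].

#' Simulate error-free paired-end reads
#'
#' Emits `round(coverage * scaffold_len / (2 * read_len))` pairs per scaffold.
#' Mate 1 is the 5' `read_len` bases of the fragment; mate 2 is the reverse
#' complement of the 3' `read_len` bases (swapped for `-`-strand fragments).
#' Reads carry no simulated errors and are exact (reverse-complemented)
#' substrings of the source genome. Deterministic given `seed`. Scaffolds
#' shorter than `read_len` are skipped with a warning.
#'
#' @param genome a [genome_assembly()].
#' @param read_len read length (default 100).
#' @param coverage target mean per-base coverage (default 2).
#' @param frag_mean,frag_sd fragment length distribution (normal, truncated).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a data frame of class `read_pairs` with columns `pair_id`,
#'   `scaffold`, `frag_start`, `frag_end`, `strand`, `mate1`, `mate2`;
#'   attributes `read_len` and `taxon`.
#' @export
simulate_read_pairs <- function(genome, read_len = 100L, coverage = 2,
                                frag_mean = 250L, frag_sd = 50,
                                seed = NULL) {
  if (coverage <= 0) parameter_error("coverage must be positive")
  if (read_len > frag_mean)
    parameter_error("read_len must not exceed frag_mean")
  read_len <- as.integer(read_len)
  with_seed(seed, {
    out <- lapply(names(genome$scaffolds), function(sid) {
      s <- genome$scaffolds[[sid]]
      L <- nchar(s)
      if (L < read_len) {
        warning(sprintf("scaffold '%s' (%d bp) shorter than read length %d: skipped",
                        sid, L, read_len), call. = FALSE)
        return(NULL)
      }
      n <- round(coverage * L / (2 * read_len))
      if (n < 1L) return(NULL)
      flen <- as.integer(round(rnorm(n, frag_mean, frag_sd)))
      flen <- pmin(pmax(flen, read_len), L)
      start <- as.integer(floor(runif(n, 0, L - flen + 1)))  # 0-based
      strand <- sample(c("+", "-"), n, replace = TRUE)
      left  <- substring(s, start + 1L, start + read_len)
      right <- revcomp(substring(s, start + flen - read_len + 1L,
                                 start + flen))
      data.frame(
        pair_id = sprintf("%s|%s|%d", genome$taxon, sid, seq_len(n)),
        scaffold = sid,
        frag_start = start,
        frag_end = start + flen,
        strand = strand,
        mate1 = ifelse(strand == "+", left, right),
        mate2 = ifelse(strand == "+", right, left),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    if (is.null(out)) out <- data.frame(
      pair_id = character(), scaffold = character(), frag_start = integer(),
      frag_end = integer(), strand = character(), mate1 = character(),
      mate2 = character(), stringsAsFactors = FALSE)
    structure(out, read_len = read_len, taxon = genome$taxon,
              class = c("read_pairs", "data.frame"))
  })
}

#' Write simulated pairs as paired FASTA (or FASTQ) files
#'
#' Writes `<prefix>_1.fasta` and `<prefix>_2.fasta` with `/1` and `/2` header
#' suffixes; with `format = "fastq"`, `.fastq` files with uniform quality `I`.
#'
#' @param pairs a `read_pairs` data frame.
#' @param prefix output path prefix.
#' @param format `"fasta"` or `"fastq"`.
#' @return character vector of the two paths, invisibly.
#' @export
write_read_fasta <- function(pairs, prefix, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  paths <- paste0(prefix, "_", 1:2, ".", format)
  for (m in 1:2) {
    ids <- paste0(pairs$pair_id, "/", m)
    seqs <- pairs[[paste0("mate", m)]]
    if (format == "fasta") {
      set <- Biostrings::BStringSet(setNames(seqs, ids))
      Biostrings::writeXStringSet(set, paths[m])
    } else {
      qual <- strrep("I", nchar(seqs))
      writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)),
                 paths[m])
    }
  }
  invisible(paths)
}

#' Read paired FASTA files back into a `read_pairs` frame
#'
#' @param path1,path2 the two mate files written by [write_read_fasta()].
#' @return a `read_pairs` data frame (fragment coordinates unknown, set NA).
#' @export
read_paired_fasta <- function(path1, path2) {
  m1 <- Biostrings::readBStringSet(path1)
  m2 <- Biostrings::readBStringSet(path2)
  if (length(m1) != length(m2))
    format_error("mate files differ in record count")
  ids <- sub("/1$", "", sub("\\s.*$", "", names(m1)))
  rl <- unique(nchar(as.character(m1)))
  structure(data.frame(
    pair_id = ids, scaffold = NA_character_,
    frag_start = NA_integer_, frag_end = NA_integer_,
    strand = NA_character_,
    mate1 = as.character(m1), mate2 = as.character(m2),
    stringsAsFactors = FALSE
  ), read_len = if (length(rl) == 1L) rl else NA_integer_,
     class = c("read_pairs", "data.frame"))
}
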