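# Genome, interval, probe and locus I/O. One coordinate convention everywhere:
# 0-based half-open (BED native); FASTA slicing uses the same convention.

#' Construct a genome assembly
#'
#' A genome assembly is an ordered set of named scaffolds of soft-masked
#' nucleotide sequence. Lowercase letters denote soft-masking; `N`/`n` denote
#' ambiguity. Scaffold ids must be unique and every scaffold non-empty.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param taxon taxon label for the assembly.
#' @return an object of class `genome_assembly`.
#' @export
#' @examples
#' g <- genome_assembly(c(s1 = "ACgtN"), taxon = "t1")
#' scaffold_lengths(g)
genome_assembly <- function(scaffolds, taxon = "unknown") {
  if (length(scaffolds) == 0L) format_error("assembly has no scaffolds")
  ids <- names(scaffolds)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    format_error("every scaffold needs a non-empty id")
  if (anyDuplicated(ids))
    format_error(sprintf("duplicate scaffold id: %s",
                         ids[duplicated(ids)][1]))
  if (any(nchar(scaffolds) < 1L))
    format_error("empty scaffold sequence")
  structure(list(taxon = as.character(taxon),
                 scaffolds = setNames(as.character(scaffolds), ids)),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> taxon '%s': %d scaffold(s), %s bp total\n",
              x$taxon, length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ",")))
  invisible(x)
}

#' Scaffold lengths of an assembly
#' @param genome a `genome_assembly`.
#' @return named integer vector of scaffold lengths.
#' @export
scaffold_lengths <- function(genome) {
  setNames(nchar(genome$scaffolds), names(genome$scaffolds))
}

#' Slice a scaffold (0-based half-open)
#'
#' @param genome a `genome_assembly`.
#' @param scaffold scaffold id.
#' @param start,end 0-based half-open coordinates.
#' @return the spanned sequence, case preserved.
#' @export
get_sequence <- function(genome, scaffold, start, end) {
  seqs <- genome$scaffolds[scaffold]
  if (anyNA(seqs))
    coordinate_error(sprintf("unknown scaffold '%s'",
                             scaffold[is.na(seqs)][1]))
  len <- nchar(seqs)
  if (any(start < 0L) || any(end > len) || any(start >= end))
    coordinate_error("interval outside scaffold bounds")
  unname(substring(seqs, start + 1L, end))
}

#' Read a (possibly gzipped) soft-masked FASTA file as a genome assembly
#'
#' Scaffold order and case (soft-masking) are preserved byte for byte. The
#' header text up to the first whitespace becomes the scaffold id.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param taxon taxon label; defaults to the file name without extension.
#' @return a [genome_assembly()].
#' @export
read_genome_fasta <- function(path, taxon = NULL) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  con <- gzfile(path, "r"); first <- readLines(con, n = 50L); close(con)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L)
    format_error(sprintf("%s: empty file (no FASTA header at line 1)", path))
  if (!startsWith(trimws(first[nonblank[1]]), ">"))
    format_error(sprintf("%s: not FASTA — line %d does not start with '>'",
                         path, nonblank[1]))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) format_error(sprintf("%s: no FASTA records", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(Biostrings::width(set) == 0L))
    format_error(sprintf("%s: empty record '%s'",
                         path, ids[Biostrings::width(set) == 0L][1]))
  if (anyDuplicated(ids))
    format_error(sprintf("%s: duplicate scaffold id '%s'",
                         path, ids[duplicated(ids)][1]))
  if (is.null(taxon))
    taxon <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  genome_assembly(setNames(as.character(set), ids), taxon = taxon)
}

#' Write a genome assembly as FASTA
#'
#' @param genome a [genome_assembly()].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 80L) {
  set <- Biostrings::BStringSet(genome$scaffolds)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct genomic intervals (0-based half-open)
#'
#' @param scaffold character vector of scaffold ids.
#' @param start,end integer coordinates, 0-based half-open.
#' @return a data frame with columns `scaffold`, `start`, `end`.
#' @export
genomic_intervals <- function(scaffold = character(), start = integer(),
                              end = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  n <- max(length(scaffold), length(start), length(end))
  if (length(scaffold) == 1L) scaffold <- rep_len(scaffold, n)
  if (length(scaffold) != length(start) || length(start) != length(end))
    parameter_error("scaffold, start, end must have equal length")
  if (anyNA(start) || anyNA(end)) format_error("non-numeric interval bound")
  if (any(start < 0L)) format_error("negative interval coordinate")
  if (any(start >= end)) format_error("interval start must be < end")
  data.frame(scaffold = as.character(scaffold), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' Requires three or more tab-separated columns; columns beyond the third are
#' ignored. Intervals are returned in file order, 0-based half-open.
#'
#' @param path path to a BED file.
#' @return a data frame of intervals (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(genomic_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    format_error(sprintf("%s: line %d has fewer than 3 tab-separated columns",
                         path, bad[1]))
  scaffold <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    format_error(sprintf("%s: non-integer coordinate at line %d",
                         path, which(is.na(start) | is.na(end))[1]))
  if (any(start < 0L))
    format_error(sprintf("%s: negative coordinate at line %d",
                         path, which(start < 0L)[1]))
  if (any(start >= end))
    format_error(sprintf("%s: empty or inverted interval at line %d",
                         path, which(start >= end)[1]))
  genomic_intervals(scaffold, start, end)
}

#' Write intervals as BED (sorted by scaffold, then start)
#'
#' @param intervals a data frame of intervals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  ord <- order(intervals$scaffold, intervals$start, intervals$end)
  df <- intervals[ord, c("scaffold", "start", "end"), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- probe and locus FASTA conventions -------------------------------------
# probe header:  uce-<n>_p<tile_index+1> |source:<taxon>
# locus header:  uce-<n>_<taxon> |uce-<n>

#' Write a probe set as FASTA
#'
#' Headers follow the convention `uce-<n>_p<tile+1> |source:<taxon>`, parseable
#' by [read_probe_fasta()].
#'
#' @param probes a probe set data frame (see [tile_probes()]).
#' @param path output path.
#' @param width FASTA line width.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path, width = 80L) {
  headers <- sprintf("%s_p%d |source:%s",
                     probes$locus_id, probes$tile_index + 1L,
                     probes$source_taxon)
  set <- Biostrings::BStringSet(setNames(toupper(probes$sequence), headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a probe FASTA written by [write_probe_fasta()]
#'
#' @param path path to a probe FASTA file.
#' @return a probe set data frame with columns `locus_id`, `source_taxon`,
#'   `tile_index`, `sequence`.
#' @export
read_probe_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  m <- regmatches(hdr, regexec("^(\\S+)_p(\\d+)\\s*\\|source:(\\S+)", hdr))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    format_error(sprintf("%s: unparseable probe header '%s'", path, hdr[bad[1]]))
  new_probe_set(data.frame(
    locus_id = vapply(m, `[[`, "", 2L),
    source_taxon = vapply(m, `[[`, "", 4L),
    tile_index = as.integer(vapply(m, `[[`, "", 3L)) - 1L,
    sequence = as.character(set),
    masked = 0L,
    ambiguous = ambiguous_count(as.character(set)) > 0L,
    stringsAsFactors = FALSE
  ))
}

#' Write captured/sliced loci as a monolithic FASTA
#'
#' One record per (locus, taxon), headers `uce-<n>_<taxon> |uce-<n>`.
#'
#' @param captured a data frame with columns `locus_id`, `taxon`, `sequence`.
#' @param path output path.
#' @param width FASTA line width.
#' @return `path`, invisibly.
#' @export
write_monolithic_locus_fasta <- function(captured, path, width = 80L) {
  headers <- sprintf("%s_%s |%s", captured$locus_id, captured$taxon,
                     captured$locus_id)
  set <- Biostrings::BStringSet(setNames(captured$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a monolithic locus FASTA written by [write_monolithic_locus_fasta()]
#'
#' @param path path to the FASTA file.
#' @return data frame with columns `locus_id`, `taxon`, `sequence`.
#' @export
read_monolithic_locus_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  m <- regmatches(hdr, regexec("^(\\S+?)_([^|[:space:]]+)\\s*\\|(\\S+)", hdr))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    format_error(sprintf("%s: unparseable locus header '%s'", path, hdr[bad[1]]))
  locus <- vapply(m, `[[`, "", 4L)
  taxon <- substring(hdr, nchar(locus) + 2L)
  taxon <- sub("\\s*\\|.*$", "", taxon)
  data.frame(locus_id = locus, taxon = taxon,
             sequence = as.character(set), stringsAsFactors = FALSE)
}
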