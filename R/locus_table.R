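# Shared-locus presence tables: combine per-exemplar conserved BED sets on
# base-genome coordinates into candidate loci with per-exemplar support, and
# apply "+k" exemplar-count selection.

new_locus_table <- function(df, exemplars) {
  structure(df, exemplars = exemplars,
            class = c("locus_presence_table", "data.frame"))
}

#' Build a shared-locus presence table from per-exemplar BED sets
#'
#' The union of all exemplars' conserved intervals is merged (gap strictly
#' less than `merge_gap`) into candidate loci; each locus's support is the set
#' of exemplars having at least one original interval overlapping it by one or
#' more bases. Locus ids `uce-1`, `uce-2`, ... are assigned in (scaffold,
#' start) order.
#'
#' @param per_exemplar_beds named list (taxon -> interval data frame).
#' @param base optional base [genome_assembly()] for bounds validation.
#' @param merge_gap merge gap in bases (default 100).
#' @return a `locus_presence_table`: data frame with columns `locus_id`,
#'   `scaffold`, `start`, `end` and list column `support`; attribute
#'   `exemplars` holds the exemplar labels in input order.
#' @export
build_presence_table <- function(per_exemplar_beds, base = NULL,
                                 merge_gap = 100L) {
  if (length(per_exemplar_beds) < 1L)
    parameter_error("need at least one exemplar BED set")
  exemplars <- names(per_exemplar_beds)
  if (is.null(exemplars) || any(exemplars == ""))
    parameter_error("per_exemplar_beds must be a named list")
  all_iv <- do.call(rbind, unname(per_exemplar_beds))
  if (is.null(all_iv) || nrow(all_iv) == 0L) {
    return(new_locus_table(data.frame(
      locus_id = character(), scaffold = character(), start = integer(),
      end = integer(), support = I(list()), stringsAsFactors = FALSE
    ), exemplars))
  }
  if (!is.null(base)) {
    lens <- scaffold_lengths(base)
    if (any(!all_iv$scaffold %in% names(lens)) ||
        any(all_iv$end > lens[all_iv$scaffold]))
      coordinate_error("exemplar interval outside base genome bounds")
  }
  loci <- merge_intervals(all_iv, merge_gap = merge_gap)
  support <- replicate(nrow(loci), character(), simplify = FALSE)
  for (tx in exemplars) {
    iv <- per_exemplar_beds[[tx]]
    if (nrow(iv) == 0L) next
    ov <- interval_overlaps(iv, loci)
    for (j in unique(ov$subject)) support[[j]] <- c(support[[j]], tx)
  }
  loci$locus_id <- sprintf("uce-%d", seq_len(nrow(loci)))
  df <- data.frame(locus_id = loci$locus_id, scaffold = loci$scaffold,
                   start = loci$start, end = loci$end,
                   stringsAsFactors = FALSE)
  df$support <- support
  new_locus_table(df, exemplars)
}

#' Select loci detected in at least `min_exemplars` exemplar genomes
#'
#' The "+k" selection: retains exactly the loci whose support set has size
#' `min_exemplars` or more (the base genome is not counted). Locus ids are
#' preserved.
#'
#' @param table a `locus_presence_table`.
#' @param min_exemplars integer in `[1, number of exemplars]`.
#' @return the filtered `locus_presence_table`.
#' @export
select_shared <- function(table, min_exemplars) {
  exemplars <- attr(table, "exemplars")
  if (length(min_exemplars) != 1L || is.na(min_exemplars) ||
      min_exemplars < 1L || min_exemplars > length(exemplars))
    parameter_error(sprintf(
      "min_exemplars must be in [1, %d]", length(exemplars)))
  keep <- lengths(table$support) >= min_exemplars
  new_locus_table(table[keep, , drop = FALSE], exemplars)
}

#' @export
print.locus_presence_table <- function(x, ...) {
  cat(sprintf("<locus_presence_table> %d loci, %d exemplars (%s)\n",
              nrow(x), length(attr(x, "exemplars")),
              paste(attr(x, "exemplars"), collapse = ", ")))
  if (nrow(x) > 0L) {
    show <- utils::head(data.frame(
      locus_id = x$locus_id, scaffold = x$scaffold, start = x$start,
      end = x$end, support = vapply(x$support, function(s)
        paste(s, collapse = ","), "")), 6L)
    print(show, row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Write / read a locus presence table as TSV
#'
#' Columns: locus_id, scaffold, start, end, support (comma-joined taxa). The
#' exemplar pool is stored in a `#exemplars:` header comment.
#'
#' @param table a `locus_presence_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#exemplars:%s",
                     paste(attr(table, "exemplars"), collapse = ",")), con)
  writeLines("locus_id\tscaffold\tstart\tend\tsupport", con)
  if (nrow(table) > 0L)
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s", table$locus_id, table$scaffold,
                       table$start, table$end,
                       vapply(table$support, function(s)
                         paste(s, collapse = ","), "")), con)
  invisible(path)
}

#' @rdname write_locus_table
#' @export
read_locus_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#exemplars:"))
    format_error(sprintf("%s: missing #exemplars header", path))
  exemplars <- strsplit(sub("^#exemplars:", "", lines[1]), ",")[[1]]
  body <- lines[-(1:2)]
  if (length(body) == 0L) {
    return(new_locus_table(data.frame(
      locus_id = character(), scaffold = character(), start = integer(),
      end = integer(), support = I(list()), stringsAsFactors = FALSE
    ), exemplars))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  df <- data.frame(
    locus_id = vapply(parts, `[[`, "", 1L),
    scaffold = vapply(parts, `[[`, "", 2L),
    start = as.integer(vapply(parts, `[[`, "", 3L)),
    end = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  df$support <- lapply(parts, function(p)
    if (length(p) >= 5L && nzchar(p[5])) strsplit(p[5], ",")[[1]]
    else character())
  new_locus_table(df, exemplars)
}
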