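# Internal helpers: classed errors, sequence utilities, seeded evaluation.

uce_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "uceforge_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

format_error    <- function(msg) uce_error("uceforge_format_error", msg)
parameter_error <- function(msg) uce_error("uceforge_parameter_error", msg)
coordinate_error <- function(msg) uce_error("uceforge_coordinate_error", msg)
usage_error     <- function(msg) uce_error("uceforge_usage_error", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement, preserving case and ambiguity codes
#'
#' Vectorised reverse complement over nucleotide strings. Lowercase
#' (soft-masked) bases stay lowercase; `N`/`n` map to themselves.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACgtN")  # "NacGT"
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtNn", "TGCAtgcaNn", x))
}

# Fraction of G/C over all bases (case-insensitive).
gc_fraction <- function(x) {
  stringi::stri_count_charclass(x, "[GCgc]") / nchar(x)
}

# Count of soft-masked (lowercase) bases.
masked_count <- function(x) {
  stringi::stri_count_charclass(x, "[a-z]")
}

# Count of bases outside the unambiguous alphabet {A,C,G,T,a,c,g,t}.
ambiguous_count <- function(x) {
  nchar(x) - stringi::stri_count_charclass(x, "[ACGTacgt]")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL evaluates code under the current RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# TRUE for character codes of A,C,G,T (uppercase): used in byte-level compares.
.acgt_codes <- local({
  v <- logical(256)
  v[utf8ToInt("A")] <- TRUE; v[utf8ToInt("C")] <- TRUE
  v[utf8ToInt("G")] <- TRUE; v[utf8ToInt("T")] <- TRUE
  v
})

# Batched Hamming distance between two equal-shape sets of fixed-width strings.
# A position counts as a mismatch when the characters differ OR either is not
# an unambiguous uppercase base (so N never supports a placement).
hamming_batch <- function(a, b, width) {
  if (length(a) == 0L) return(integer(0))
  ai <- utf8ToInt(paste(a, collapse = ""))
  bi <- utf8ToInt(paste(b, collapse = ""))
  bad <- (ai != bi) | !.acgt_codes[ai] | !.acgt_codes[bi]
  as.integer(colSums(matrix(bad, nrow = width)))
}
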