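# Exact k-mer machinery shared by the read mapper, align-back and capture
# stages. k-mers over {A,C,G,T} are encoded base-4 into doubles (exact up to
# k = 26, since 4^26 < 2^53); windows containing any other character get NA.

.base_code <- local({
  v <- rep(NA_real_, 256)
  v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
  v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
  v
})

# Rolling k-mer codes over a single (uppercase) string: codes[i] encodes the
# window starting at 0-based position i-1. Length n-k+1; NA where ambiguous.
kmer_codes <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(numeric(0))
  v <- .base_code[utf8ToInt(s)]
  m <- n - k + 1L
  code <- v[seq_len(m)]
  for (j in 2:k) code <- code * 4 + v[seq.int(j, m + j - 1L)]
  code
}

# Sorted k-mer index over the scaffolds of a genome (case-insensitive).
# Fields: codes (sorted), scaf (integer scaffold index), pos (0-based start),
# scaffold_ids, k.
kmer_index <- function(genome, k = 20L) {
  ids <- names(genome$scaffolds)
  per <- lapply(seq_along(ids), function(i) {
    cd <- kmer_codes(toupper(genome$scaffolds[[i]]), k)
    keep <- !is.na(cd)
    list(code = cd[keep], scaf = rep.int(i, sum(keep)),
         pos = (which(keep) - 1L))
  })
  code <- unlist(lapply(per, `[[`, "code"), use.names = FALSE)
  scaf <- unlist(lapply(per, `[[`, "scaf"), use.names = FALSE)
  pos  <- unlist(lapply(per, `[[`, "pos"), use.names = FALSE)
  o <- order(code)
  structure(list(codes = code[o], scaf = scaf[o], pos = pos[o],
                 scaffold_ids = ids, k = as.integer(k)),
            class = "kmer_index")
}

# Look up query codes in a sorted index. Returns data.frame(query, scaf, pos)
# with one row per (query, occurrence); NA queries yield nothing.
kmer_lookup <- function(index, query_codes) {
  q <- query_codes
  ok <- which(!is.na(q))
  if (length(ok) == 0L || length(index$codes) == 0L)
    return(data.frame(query = integer(), scaf = integer(), pos = integer()))
  qs <- q[ok]
  hi <- findInterval(qs, index$codes)
  lo <- findInterval(qs - 0.5, index$codes)
  n <- hi - lo
  keep <- n > 0L
  if (!any(keep))
    return(data.frame(query = integer(), scaf = integer(), pos = integer()))
  idx <- sequence(n[keep], from = lo[keep] + 1L)
  data.frame(query = rep.int(ok[keep], n[keep]),
             scaf = index$scaf[idx],
             pos = index$pos[idx])
}
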