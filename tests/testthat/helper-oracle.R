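# Independent brute-force scorer for converted-space alignment: scores the
# read at EVERY ungapped offset of a reference string (match +1, mismatch
# -2, N always a mismatch) and returns the best score. Deliberately written
# with plain character comparison, sharing no code with the aligner.
oracle_best_score <- function(read, ref, match = 1L, mispen = 2L) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  L <- length(rd)
  n <- length(rf)
  if (n < L) return(list(score = -Inf, offsets = integer(0), mm = NA))
  best <- -Inf; offs <- integer(0); best_mm <- NA_integer_
  for (o in 0:(n - L)) {
    w <- rf[(o + 1):(o + L)]
    mm <- sum(w != rd | w == "N" | rd == "N")
    sc <- (L - mm) * match - mm * mispen
    if (sc > best) {
      best <- sc; offs <- o; best_mm <- mm
    } else if (sc == best) {
      offs <- c(offs, o)
    }
  }
  list(score = best, offsets = offs, mm = best_mm)
}

# Does a clean (exact, N-free) seed exist for the read at offset `o`, with
# seeds at stride k from 0 plus one flush with the read end?
oracle_clean_seed <- function(read, ref, o, k) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  L <- length(rd)
  seeds <- unique(c(seq(0, L - k, by = k), L - k))
  for (s in seeds) {
    rs <- rd[(s + 1):(s + k)]
    ws <- rf[(o + s + 1):(o + s + k)]
    if (!any(rs == "N") && all(rs == ws)) return(TRUE)
  }
  FALSE
}

# Random base string helper used across property tests.
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
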