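# Independent brute-force LZ76 oracle: literal exhaustive-history parse.
# A phrase s[l..l+j] ends at the first j where it does not occur as a
# substring of s[1..l+j-1] (occurrences may overlap the phrase); the
# final phrase counts even when unterminated. Deliberately naive - no
# shared code with the package routine.
lz_brute <- function(s) {
  n <- length(s)
  has_sub <- function(text, pat) {
    lp <- length(pat); lt <- length(text)
    if (lp > lt) return(FALSE)
    for (st in 1:(lt - lp + 1)) if (all(text[st:(st + lp - 1)] == pat)) return(TRUE)
    FALSE
  }
  cnt <- 0L; l <- 1L
  while (l <= n) {
    j <- 0L; unterminated <- FALSE
    repeat {
      if (l + j > n) { unterminated <- TRUE; break }
      if (!has_sub(s[seq_len(l + j - 1L)], s[l:(l + j)])) break
      j <- j + 1L
    }
    cnt <- cnt + 1L
    l <- if (unterminated) n + 1L else l + j + 1L
  }
  cnt
}

# short protocol for desk-scale decoding tests: 30 four-second LZc
# epochs each of rest and SBminus, interleaved in 12 s segments so every
# chronological split block holds both states in balance (the full
# protocol achieves the same through its 60 s alternations)
mini_protocol <- function(sampling_rate = 300)
  session_protocol(rep(c("rest", "SBminus"), 10),
                   rep(12, 20), sampling_rate)

# small feature table with planted class separation for decoder tests
toy_table <- function(n = 120, p = 4, delta = 0, seed = 1,
                      participant = "P01") {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  state <- rep(c("SBminus", "rest"), length.out = n)
  x[state == "SBminus", ] <- x[state == "SBminus", ] + delta
  df <- data.frame(participant = participant, state = state,
                   epoch_idx = seq_len(n), stringsAsFactors = FALSE)
  colnames(x) <- paste0("f__", seq_len(p))
  feature_table(cbind(df, as.data.frame(x)))
}
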