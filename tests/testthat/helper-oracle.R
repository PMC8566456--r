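# Independent semi-global affine-gap score oracle: a plain Gotoh DP written
# directly from the recurrences, score-only, vectorised across sequence
# pairs of equal dimensions. Free reference overhangs; the read is aligned
# end to end; a gap run of length k costs |open| + (k - 1) * |ext|.
oracle_semiglobal_scores <- function(reads, refs, match = 2, mismatch = -2,
                                     open = -6, ext = -1) {
  stopifnot(length(reads) == length(refs))
  out <- numeric(length(reads))
  grp <- paste(nchar(reads), nchar(refs))
  NEG <- -1e9
  for (g in unique(grp)) {
    idx <- which(grp == g)
    m <- nchar(reads[idx[1]])
    n <- nchar(refs[idx[1]])
    np <- length(idx)
    R <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE)), np, m,
                byrow = TRUE)
    X <- matrix(unlist(strsplit(refs[idx], "", fixed = TRUE)), np, n,
                byrow = TRUE)
    Hprev <- matrix(NEG, np, m + 1)
    Hprev[, 1] <- 0
    if (m > 0) {
      Hprev[, 1 + seq_len(m)] <- matrix(rep(open + (seq_len(m) - 1) * ext,
                                            each = np), np)
    }
    Eprev <- matrix(NEG, np, m + 1)
    best <- Hprev[, m + 1]
    for (i in seq_len(n)) {
      Hcur <- matrix(NEG, np, m + 1)
      Ecur <- matrix(NEG, np, m + 1)
      Fcur <- matrix(NEG, np, m + 1)
      Hcur[, 1] <- 0  # free reference prefix
      for (j in seq_len(m)) {
        Ecur[, j + 1] <- pmax(Hprev[, j + 1] + open, Eprev[, j + 1] + ext)
        Fcur[, j + 1] <- pmax(Hcur[, j] + open, Fcur[, j] + ext)
        s <- ifelse(X[, i] == R[, j] & X[, i] != "N", match, mismatch)
        Hcur[, j + 1] <- pmax(Hprev[, j] + s,
                              pmax(Ecur[, j + 1], Fcur[, j + 1]))
      }
      best <- pmax(best, Hcur[, m + 1])
      Hprev <- Hcur
      Eprev <- Ecur
    }
    out[idx] <- best
  }
  out
}

# all sequences over an alphabet up to a maximum length
all_seqs <- function(max_len, alphabet = c("A", "C")) {
  unlist(lapply(seq_len(max_len), function(L) {
    do.call(paste0, expand.grid(rep(list(alphabet), L),
                                stringsAsFactors = FALSE))
  }))
}
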