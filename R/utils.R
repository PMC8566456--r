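DNA_BASES <- c("A", "C", "G", "T")

# complement that tolerates N and gap characters
comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[x])
}

revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(comp_base(strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

check_dna <- function(x, what, allow_n = FALSE, len = NULL) {
  if (!is.character(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a character vector of DNA without NA", what))
  }
  if (!all(is_dna(x, allow_n = allow_n))) {
    abort(sprintf("`%s` contains non-DNA characters (allowed: A/C/G/T%s)",
                  what, if (allow_n) "/N" else ""))
  }
  if (!is.null(len) && !all(nchar(x) == len)) {
    abort(sprintf("`%s` must have length %d nt", what, len))
  }
  invisible(x)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# division that returns NA (the explicit undefined marker) on a 0 denominator
safe_div <- function(num, den) {
  n <- max(length(num), length(den))
  num <- rep_len(as.numeric(num), n)
  den <- rep_len(as.numeric(den), n)
  out <- num / den
  out[is.na(den) | den == 0] <- NA_real_
  out
}
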