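# Standard synthetic reporter amplicon used across tests.
#
# Layout (0-based coordinates):
#   0..29   exon, ending in the canonical 5' flank G at coord 29
#   30..31  inactivated donor dinucleotide "AC"
#   32..35  canonical 3' flank "AAGT"
#   36..    intron
# Protospacer [26, 46) on the + strand puts the donor A at protospacer
# position 5 and the donor C at position 6; PAM "TGG" at [46, 49);
# cut site (protospacer position 17) at coord 42.

test_exon <- "ATCGATTACGATCACTGATCAAGCTTAGCG"
test_reference <- paste0(
  test_exon,          # 0..29
  "AC",               # donor, 30..31
  "AAGT",             # 3' flank, 32..35
  "CATTCACTTC",       # intron, 36..45
  "TGG",              # PAM, 46..48
  "ATCGTACGATCATCGATACGTTAGCA")  # intron tail, 49..74

stopifnot(nchar(test_reference) == 75,
          substr(test_reference, 30, 30) == "G",   # flank5 at coord 29
          substr(test_reference, 31, 32) == "AC",
          substr(test_reference, 33, 36) == "AAGT",
          substr(test_reference, 48, 49) == "GG")

abe_site <- function() {
  target_site(test_reference, proto_start = 26,
              editable_positions = data.frame(position = 30, from = "A",
                                              to = "G"))
}

cbe_site <- function() {
  target_site(test_reference, proto_start = 26,
              editable_positions = data.frame(position = 31, from = "C",
                                              to = "T"))
}

# bystander positions: the two As of the 3' AAGT flank
bystander_positions <- c(32L, 33L)

# reference with a base substituted (0-based coordinate)
with_sub <- function(seq, pos, base) {
  substr(seq, pos + 1, pos + 1) <- base
  seq
}

# reference with k bases deleted starting at 0-based coordinate
with_del <- function(seq, pos, k = 1) {
  paste0(substr(seq, 1, pos), substr(seq, pos + k + 1, nchar(seq)))
}

# reference with bases inserted before 0-based coordinate
with_ins <- function(seq, pos, bases) {
  paste0(substr(seq, 1, pos), bases, substr(seq, pos + 1, nchar(seq)))
}

# read with k substitutions spread across the first 20 reference positions
# (non-contiguous, so isolated mismatches stay substitutions in the
# optimal alignment)
make_sub_read <- function(k) {
  rd <- test_reference
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  if (k > 0) {
    for (p in seq(0, by = 2, length.out = k)) {
      rd <- with_sub(rd, p, flip[[substr(test_reference, p + 1, p + 1)]])
    }
  }
  rd
}
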