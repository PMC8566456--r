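#' A ready-made reporter target site for examples and pipelines
#'
#' Builds the packaged example amplicon: a split-fluorophore reporter
#' junction with a 30-nt exon ending in the canonical G flank, the
#' inactivated `AC` donor dinucleotide at coordinates 30-31, the canonical
#' `AAGT` 3' flank at 32-35, and an intron carrying an NGG PAM so that the
#' protospacer (coordinates 26-45, + strand) places the donor adenine at
#' protospacer position 5 and the donor cytosine at position 6; the cut
#' site falls at coordinate 42.
#'
#' @param editor `"ABE"` (target the donor A, expecting A to G) or `"CBE"`
#'   (target the donor C, expecting C to T).
#' @return A [target_site()] with one designated editable position.
#' @examples
#' site <- example_reporter_site("ABE")
#' site$cut_site
#' @export
example_reporter_site <- function(editor = c("ABE", "CBE")) {
  editor <- match.arg(editor)
  reference <- paste0(
    "ATCGATTACGATCACTGATCAAGCTTAGCG",  # exon, 0..29
    "AC",                              # inactivated donor, 30..31
    "AAGT",                            # 3' flank, 32..35
    "CATTCACTTC",                      # intron, 36..45
    "TGG",                             # PAM, 46..48
    "ATCGTACGATCATCGATACGTTAGCA")      # intron tail, 49..74
  ed <- if (editor == "ABE") {
    tibble(position = 30L, from = "A", to = "G")
  } else {
    tibble(position = 31L, from = "C", to = "T")
  }
  target_site(reference, proto_start = 26L, editable_positions = ed)
}
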