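#' Build a splice-donor context
#'
#' A splice donor context is the donor dinucleotide (intron positions +1/+2,
#' canonically `GT`) together with its last exonic base (`flank5`, canonically
#' `G`) and the first four intronic bases after the donor (`flank3`,
#' canonically `RAGT` with `R` = A or G). Intron sequence beyond `flank3` does
#' not enter the activity rule and may be arbitrary.
#'
#' @param donor 2-nt donor dinucleotide(s).
#' @param flank5 1-nt exonic flank(s); canonical when `G`.
#' @param flank3 4-nt intronic flank(s); canonical when matching `RAGT`.
#' @return A tibble with columns `donor`, `flank5`, `flank3`,
#'   `flank5_canonical`, `flank3_canonical` and `class`
#'   (`"active"`/`"inactive"`).
#' @examples
#' splice_donor_context("GT")               # the canonical active junction
#' splice_donor_context("AC")               # the dual-editable inactive donor
#' @export
splice_donor_context <- function(donor, flank5 = "G", flank3 = "AAGT") {
  check_dna(donor, "donor", len = 2L)
  check_dna(flank5, "flank5", len = 1L)
  check_dna(flank3, "flank3", len = 4L)
  ctx <- tibble(donor = donor, flank5 = flank5, flank3 = flank3) |>
    mutate(flank5_canonical = .data$flank5 == "G",
           flank3_canonical = grepl("^[AG]AGT$", .data$flank3))
  ctx$class <- classify_splice_donor(ctx)
  ctx
}

#' Classify a splice donor context as active or inactive
#'
#' Binary activity rule for the 5' splice site of the reporter intron,
#' derived from a mutational scan of the donor and its flanks: with both
#' flanks canonical, the canonical `GT` donor and every single-base variant
#' of it support splicing; altering one donor base together with either
#' flank, both donor bases, or both flanks (even with a canonical `GT`)
#' abolishes it. Formally, with `d` the Hamming distance of the donor to
#' `GT` and `f` the number of non-canonical flanks, the context is active
#' iff `d == 0 & f <= 1` or `d == 1 & f == 0`.
#'
#' @param x Either a data frame with columns `donor`, `flank5`, `flank3`
#'   (e.g. from [splice_donor_context()]), or a character vector of donor
#'   dinucleotides.
#' @param flank5,flank3 Flanks used when `x` is a character vector.
#' @param ... Unused.
#' @return A character vector, `"active"` or `"inactive"`.
#' @examples
#' classify_splice_donor("GT")                       # active
#' classify_splice_donor("AC")                       # inactive, editable
#' classify_splice_donor("GT", flank5 = "C", flank3 = "CCCC")  # inactive
#' @export
classify_splice_donor <- function(x, ...) UseMethod("classify_splice_donor")

#' @rdname classify_splice_donor
#' @export
classify_splice_donor.data.frame <- function(x, ...) {
  stopifnot(all(c("donor", "flank5", "flank3") %in% names(x)))
  classify_splice_donor(x$donor, flank5 = x$flank5, flank3 = x$flank3)
}

#' @rdname classify_splice_donor
#' @export
classify_splice_donor.character <- function(x, flank5 = "G",
                                            flank3 = "AAGT", ...) {
  check_dna(x, "donor", len = 2L)
  check_dna(flank5, "flank5", len = 1L)
  check_dna(flank3, "flank3", len = 4L)
  d <- (substr(x, 1, 1) != "G") + (substr(x, 2, 2) != "T")
  f <- (flank5 != "G") + !grepl("^[AG]AGT$", flank3)
  ifelse((d == 0 & f <= 1) | (d == 1 & f == 0), "active", "inactive")
}

editor_substrate <- c(ABE = "A", CBE = "C", CBE_byproduct = "C")
editor_product <- c(ABE = "G", CBE = "T", CBE_byproduct = "G")

#' Apply a base-editing conversion to a sequence
#'
#' Applies the editor's canonical conversion (`ABE`: A\eqn{\to}G, `CBE`:
#' C\eqn{\to}T, `CBE_byproduct`: the minority C\eqn{\to}G outcome) at the
#' requested positions. Positions that do not hold the editor's substrate
#' base are left unchanged and reported back in the `skipped` attribute;
#' the operation is therefore idempotent for a fixed position set.
#'
#' @param seq A single DNA string.
#' @param editor `"ABE"`, `"CBE"` or `"CBE_byproduct"`.
#' @param positions 0-based positions in `seq` to edit.
#' @return The edited sequence, with attribute `skipped` holding the 0-based
#'   positions that did not carry the substrate base.
#' @examples
#' apply_base_edit("AC", "ABE", 0)   # "GC"
#' apply_base_edit("AC", "CBE", 1)   # "AT"
#' @export
apply_base_edit <- function(seq, editor = c("ABE", "CBE", "CBE_byproduct"),
                            positions = integer()) {
  editor <- match.arg(editor)
  stopifnot(is.character(seq), length(seq) == 1L)
  check_dna(seq, "seq", allow_n = TRUE)
  positions <- as.integer(positions)
  if (length(positions) &&
      (min(positions) < 0L || max(positions) >= nchar(seq))) {
    abort("`positions` must be 0-based indices inside `seq`")
  }
  v <- chars(seq)
  hit <- positions[v[positions + 1L] == editor_substrate[[editor]]]
  v[hit + 1L] <- editor_product[[editor]]
  structure(paste(v, collapse = ""), skipped = setdiff(positions, hit))
}

#' Enumerate donors convertible from inactive to active by one base edit
#'
#' Scans all 16 donor dinucleotides under fixed flanks, keeps those
#' classified inactive, and finds every single canonical conversion
#' (A\eqn{\to}G for ABE, C\eqn{\to}T for CBE) that yields an active donor.
#' With `editor = "both"` only donors rescuable by ABE and, independently,
#' by CBE are kept — with canonical flanks that is exactly the `AC` donor
#' (ABE at position 1 gives `GC`, CBE at position 2 gives `AT`), the basis
#' of the dual-editor reporter.
#'
#' @param editor `"ABE"`, `"CBE"` or `"both"`.
#' @param flank5,flank3 Flanks shared by the inactive and active context
#'   (canonical by default).
#' @return A tibble with one row per (donor, conversion): `inactive_donor`,
#'   `editor`, `edited_donor_position` (1 or 2), `conversion_from`,
#'   `conversion_to`, `active_donor`, `flank5`, `flank3`.
#' @examples
#' enumerate_reporter_pairs("both")
#' @export
enumerate_reporter_pairs <- function(editor = c("ABE", "CBE", "both"),
                                     flank5 = "G", flank3 = "AAGT") {
  editor <- match.arg(editor)
  donors <- donor_grid()
  inactive <- donors[classify_splice_donor(donors, flank5, flank3) ==
                       "inactive"]
  one_editor <- function(ed) {
    res <- list()
    for (don in inactive) {
      for (pos in 1:2) {
        if (substr(don, pos, pos) != editor_substrate[[ed]]) next
        edited <- apply_base_edit(don, ed, pos - 1L)
        if (classify_splice_donor(as.character(edited), flank5,
                                  flank3) == "active") {
          res[[length(res) + 1L]] <- tibble(
            inactive_donor = don, editor = ed,
            edited_donor_position = pos,
            conversion_from = editor_substrate[[ed]],
            conversion_to = editor_product[[ed]],
            active_donor = as.character(edited),
            flank5 = flank5, flank3 = flank3)
        }
      }
    }
    bind_rows(res)
  }
  if (editor != "both") {
    out <- one_editor(editor)
  } else {
    abe <- one_editor("ABE")
    cbe <- one_editor("CBE")
    keep <- intersect(abe$inactive_donor, cbe$inactive_donor)
    out <- bind_rows(abe, cbe) |> filter(.data$inactive_donor %in% keep)
  }
  if (nrow(out) == 0) {
    return(tibble(inactive_donor = character(), editor = character(),
                  edited_donor_position = integer(),
                  conversion_from = character(), conversion_to = character(),
                  active_donor = character(), flank5 = character(),
                  flank3 = character()))
  }
  arrange(out, .data$inactive_donor, .data$editor,
          .data$edited_donor_position)
}

donor_grid <- function() {
  as.vector(outer(DNA_BASES, DNA_BASES, paste0))
}

#' Describe a protospacer target site on a reference amplicon
#'
#' Bundles the reference amplicon with the protospacer/PAM coordinates, the
#' cut-site coordinate, the designated editable positions and the editing
#' window. All coordinates are 0-based; half-open intervals; protospacer
#' *positions* (for the editing window) are 1-based counting from the
#' PAM-distal end, the usual base-editing convention. The cut site is the
#' reference coordinate of protospacer position 17, i.e. the base on the
#' PAM-distal side of the blunt-cut bond between positions 17 and 18 of a
#' 20-nt spacer.
#'
#' @param reference DNA string of the reference amplicon.
#' @param proto_start 0-based start of the protospacer on the reference.
#' @param strand `"+"` or `"-"`: strand of the protospacer.
#' @param protospacer_len Protospacer length (default 20).
#' @param editable_positions Data frame with columns `position` (0-based
#'   reference coordinate), `from`, `to` (bases on the reference strand).
#' @param editing_window Inclusive protospacer-position interval,
#'   default `c(4, 8)`.
#' @param check_pam Require an NGG PAM adjacent to the protospacer.
#' @return A list of class `target_site`.
#' @export
target_site <- function(reference, proto_start, strand = "+",
                        protospacer_len = 20L, editable_positions = NULL,
                        editing_window = c(4L, 8L), check_pam = TRUE) {
  check_dna(reference, "reference")
  proto_start <- as.integer(proto_start)
  protospacer_len <- as.integer(protospacer_len)
  stopifnot(strand %in% c("+", "-"), length(editing_window) == 2,
            editing_window[1] >= 1, editing_window[2] >= editing_window[1])
  len <- nchar(reference)
  proto_end <- proto_start + protospacer_len
  if (proto_start < 0 || proto_end > len) {
    abort("protospacer interval falls outside the reference")
  }
  if (strand == "+") {
    pam_start <- proto_end
    pam_end <- proto_end + 3L
    cut_site <- proto_start + protospacer_len - 4L
  } else {
    pam_start <- proto_start - 3L
    pam_end <- proto_start
    cut_site <- proto_start + 3L
  }
  if (pam_start < 0 || pam_end > len) abort("PAM interval falls outside the reference")
  if (check_pam) {
    pam <- substr(reference, pam_start + 1L, pam_end)
    ok <- if (strand == "+") grepl("^.GG$", pam) else grepl("^CC.$", pam)
    if (!ok) abort(sprintf("no NGG PAM at [%d, %d) on strand %s", pam_start,
                           pam_end, strand))
  }
  ed <- editable_positions
  if (is.null(ed)) {
    ed <- tibble(position = integer(), from = character(), to = character())
  } else {
    ed <- as_tibble(ed)
    stopifnot(all(c("position", "from", "to") %in% names(ed)))
    ed$position <- as.integer(ed$position)
    if (any(ed$position < 0 | ed$position >= len)) {
      abort("editable positions fall outside the reference")
    }
    obs <- substring(reference, ed$position + 1L, ed$position + 1L)
    if (!all(obs == ed$from)) {
      abort("reference does not carry `from` at every editable position")
    }
  }
  structure(list(reference = reference, proto_start = proto_start,
                 proto_end = proto_end, pam_start = pam_start,
                 pam_end = pam_end, strand = strand,
                 protospacer_len = protospacer_len, cut_site = cut_site,
                 editable_positions = ed,
                 editing_window = as.integer(editing_window)),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf(paste0("<target_site> %d-nt reference, protospacer [%d, %d) ",
                     "strand %s, PAM [%d, %d), cut site %d\n"),
              nchar(x$reference), x$proto_start, x$proto_end, x$strand,
              x$pam_start, x$pam_end, x$cut_site))
  if (nrow(x$editable_positions)) {
    cat("  editable:",
        paste(sprintf("%d %s>%s", x$editable_positions$position,
                      x$editable_positions$from, x$editable_positions$to),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# 1-based protospacer position (from the PAM-distal end) of a reference
# coordinate, NA outside the protospacer.
proto_position <- function(site, coord) {
  pos <- if (site$strand == "+") coord - site$proto_start + 1L
         else site$proto_end - coord
  ifelse(pos >= 1L & pos <= site$protospacer_len, pos, NA_integer_)
}

#' Enumerate PAM placements covering an edited base
#'
#' Scans both strands of a reference for NGG PAMs whose protospacer places
#' the edited base inside the editing window (1-based protospacer positions
#' counted from the PAM-distal end, inclusive on both ends). Because the
#' reporter tolerates arbitrary intron sequence downstream of the 3' flank,
#' the PAM — and with it the editing window — can be moved freely relative
#' to the edited base; this enumerates the placements available on a given
#' backbone.
#'
#' @param reference DNA string.
#' @param edited_position 0-based reference coordinate of the edited base.
#' @param window Inclusive protospacer-position interval, default `c(4, 8)`.
#' @param protospacer_len Protospacer length (default 20).
#' @return A tibble sorted by `proto_start` then strand, one row per
#'   placement, with protospacer/PAM/cut coordinates and the protospacer
#'   position at which the edited base sits; `sites` carries the
#'   corresponding `target_site` objects as a list column.
#' @export
enumerate_pam_placements <- function(reference, edited_position,
                                     window = c(4L, 8L),
                                     protospacer_len = 20L) {
  check_dna(reference, "reference")
  len <- nchar(reference)
  if (len < protospacer_len + 3L) {
    abort("reference shorter than protospacer + PAM")
  }
  edited_position <- as.integer(edited_position)
  stopifnot(edited_position >= 0, edited_position < len)
  v <- chars(reference)
  rows <- list()
  # + strand: PAM [p, p+3) with GG at p+1, protospacer ends at p
  for (p in seq_len(len - 2L) - 1L) {
    if (p - protospacer_len < 0L || p + 3L > len) next
    if (v[p + 2L] != "G" || v[p + 3L] != "G") next
    ps <- p - protospacer_len
    pos <- edited_position - ps + 1L
    if (pos >= window[1] && pos <= window[2]) {
      rows[[length(rows) + 1L]] <- tibble(strand = "+", proto_start = ps,
                                          pam_start = p, proto_position = pos)
    }
  }
  # - strand: NGG on the minus strand reads CCN on the reference
  for (p in seq_len(len - 2L) - 1L) {
    if (p + 3L + protospacer_len > len) next
    if (v[p + 1L] != "C" || v[p + 2L] != "C") next
    ps <- p + 3L
    pos <- ps + protospacer_len - edited_position
    if (pos >= window[1] && pos <= window[2]) {
      rows[[length(rows) + 1L]] <- tibble(strand = "-", proto_start = ps,
                                          pam_start = p, proto_position = pos)
    }
  }
  if (!length(rows)) {
    return(tibble(strand = character(), proto_start = integer(),
                  proto_end = integer(), pam_start = integer(),
                  pam_end = integer(), cut_site = integer(),
                  proto_position = integer(), sites = list()))
  }
  out <- bind_rows(rows) |>
    arrange(.data$proto_start, .data$strand) |>
    mutate(proto_end = .data$proto_start + protospacer_len,
           pam_end = .data$pam_start + 3L)
  out$sites <- purrr::pmap(out[c("proto_start", "strand")], function(
      proto_start, strand) {
    target_site(reference, proto_start, strand,
                protospacer_len = protospacer_len,
                editing_window = as.integer(window))
  })
  out$cut_site <- vapply(out$sites, function(s) s$cut_site, integer(1))
  select(out, "strand", "proto_start", "proto_end", "pam_start", "pam_end",
         "cut_site", "proto_position", "sites")
}
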