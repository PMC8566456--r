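#' Alignment scoring parameters
#'
#' Affine-gap scoring used by the semi-global aligner. A gap run of length
#' `k` scores `gap_open + (k - 1) * gap_extend`, i.e. the opening penalty
#' already covers the first gapped base, so a single-base indel costs
#' `|gap_open|`.
#'
#' @param match Score for a matching base pair (default `2`).
#' @param mismatch Score for a substitution (default `-2`). `N` never matches
#'   and always scores as a substitution.
#' @param gap_open Score for the first base of a gap run (default `-6`).
#' @param gap_extend Score for each further gapped base (default `-1`).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -2L, gap_open = -6L,
                          gap_extend = -1L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Semi-global alignment of a read to a reference amplicon
#'
#' Aligns the full read against the reference with free reference overhangs
#' (glocal alignment) under affine-gap scoring. Score ties are broken by
#' preferring substitutions over gaps, and every gap run in the returned
#' alignment is left-aligned: it cannot be shifted one base toward the
#' reference 5' end without changing the aligned base content.
#'
#' @param read,reference Non-empty DNA strings (A/C/G/T/N).
#' @param scoring An [align_scoring()] object.
#' @param read_id Identifier stored on the result.
#' @return A `read_alignment` object: a list with `read_id`, `score`,
#'   `ref_start`/`ref_end` (0-based half-open reference span covered),
#'   the gapped `ref_aln`/`read_aln` rows, and an `events` tibble with one
#'   row per run of `match`, `substitution`, `insertion` or `deletion`
#'   (0-based half-open `ref_start`/`ref_end`, `read_start`/`read_end`,
#'   plus the run's bases). Insertions have an empty reference interval,
#'   deletions an empty read interval.
#' @examples
#' aln <- align_semi_global("ACGT", "TTACGTTT")
#' aln$score
#' tidy(aln)
#' @export
align_semi_global <- function(read, reference, scoring = align_scoring(),
                              read_id = "read") {
  if (!is.character(read) || length(read) != 1L || nchar(read) == 0L ||
      !is.character(reference) || length(reference) != 1L ||
      nchar(reference) == 0L) {
    abort("`read` and `reference` must be single non-empty DNA strings")
  }
  check_dna(read, "read", allow_n = TRUE)
  check_dna(reference, "reference", allow_n = TRUE)
  raw <- .cpp_align_semiglobal(read, reference, scoring$match,
                               scoring$mismatch, scoring$gap_open,
                               scoring$gap_extend)
  new_read_alignment(read_id, read, reference, raw$score[1], raw$ref_start[1],
                     raw$ref_end[1], raw$ref_aln[1], raw$read_aln[1], scoring)
}

new_read_alignment <- function(read_id, read, reference, score, ref_start,
                               ref_end, ref_aln, read_aln, scoring) {
  structure(list(read_id = read_id, read = read, reference = reference,
                 score = score,
                 ref_start = ref_start, ref_end = ref_end,
                 ref_aln = ref_aln, read_aln = read_aln,
                 events = aln_events(ref_aln, read_aln, ref_start),
                 scoring = scoring),
            class = "read_alignment")
}

# Decompose a pair of gapped rows into run-length events.
aln_events <- function(ref_aln, read_aln, ref_offset) {
  if (nchar(ref_aln) == 0L) {
    return(tibble(kind = character(), ref_start = integer(),
                  ref_end = integer(), read_start = integer(),
                  read_end = integer(), ref_bases = character(),
                  read_bases = character()))
  }
  a <- chars(ref_aln)
  b <- chars(read_aln)
  kind <- ifelse(a == "-", "insertion",
          ifelse(b == "-", "deletion",
          ifelse(a == b & a != "N", "match", "substitution")))
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  refc <- ref_offset + c(0L, cumsum(a != "-"))   # ref coord before column i
  readc <- c(0L, cumsum(b != "-"))
  tibble(
    kind = r$values,
    ref_start = refc[starts],
    ref_end = refc[ends + 1L],
    read_start = readc[starts],
    read_end = readc[ends + 1L],
    ref_bases = vapply(seq_along(starts), function(k) {
      paste(a[starts[k]:ends[k]][a[starts[k]:ends[k]] != "-"], collapse = "")
    }, character(1)),
    read_bases = vapply(seq_along(starts), function(k) {
      paste(b[starts[k]:ends[k]][b[starts[k]:ends[k]] != "-"], collapse = "")
    }, character(1))
  )
}

#' Left-align the gap runs of an alignment
#'
#' Rewrites an alignment so that every gap run sits as far toward the
#' reference 5' end as possible without changing the aligned base content.
#' Aligner output is already in this canonical form; the operation is
#' idempotent.
#'
#' @param aln A `read_alignment` object.
#' @return A `read_alignment` object in canonical (left-aligned) gap form.
#' @export
left_align <- function(aln) {
  stopifnot(inherits(aln, "read_alignment"))
  shifted <- .cpp_left_align(aln$ref_aln, aln$read_aln)
  new_read_alignment(aln$read_id, aln$read, aln$reference, aln$score,
                     aln$ref_start, aln$ref_end, shifted$ref_aln,
                     shifted$read_aln, aln$scoring)
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> %s  score %d  ref [%d, %d)\n", x$read_id,
              x$score, x$ref_start, x$ref_end))
  cat("  ref : ", x$ref_aln, "\n", sep = "")
  cat("  read: ", x$read_aln, "\n", sep = "")
  invisible(x)
}

#' Tidy an alignment into its event table
#'
#' @param x A `read_alignment` object.
#' @param ... Unused.
#' @return A tibble of alignment events (see [align_semi_global()]).
#' @importFrom generics tidy
#' @export
tidy.read_alignment <- function(x, ...) {
  mutate(x$events, read_id = x$read_id, .before = 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Batch alignment of many reads against one reference; returns a tibble.
# With auto_orient = TRUE a read is flipped to its reverse complement when
# the flipped alignment scores better by at least |gap_open|.
align_batch <- function(seqs, reference, scoring = align_scoring(),
                        read_ids = NULL, auto_orient = FALSE) {
  read_ids <- read_ids %||% sprintf("read%06d", seq_along(seqs))
  fwd <- .cpp_align_semiglobal(seqs, reference, scoring$match,
                               scoring$mismatch, scoring$gap_open,
                               scoring$gap_extend)
  orientation <- rep("+", length(seqs))
  if (auto_orient && length(seqs) > 0) {
    rc <- revcomp(seqs)
    rev <- .cpp_align_semiglobal(rc, reference, scoring$match,
                                 scoring$mismatch, scoring$gap_open,
                                 scoring$gap_extend)
    flip <- rev$score >= fwd$score + abs(scoring$gap_open)
    if (any(flip)) {
      for (fld in c("score", "ref_start", "ref_end", "ref_aln", "read_aln")) {
        fwd[[fld]][flip] <- rev[[fld]][flip]
      }
      orientation[flip] <- "-"
    }
  }
  # span: for every reference column covered, the read character ('-' if
  # deleted); insertions do not occupy reference columns
  span <- vapply(seq_along(seqs), function(k) {
    a <- chars(fwd$ref_aln[k])
    b <- chars(fwd$read_aln[k])
    paste(b[a != "-"], collapse = "")
  }, character(1))
  tibble(read_id = read_ids, seq = seqs, orientation = orientation,
         score = fwd$score, ref_start = fwd$ref_start,
         ref_end = fwd$ref_end, ref_aln = fwd$ref_aln,
         read_aln = fwd$read_aln, span = span)
}

# Read base observed at 0-based reference coordinate `pos` for each row of an
# align_batch() tibble: "." not covered, "-" deleted, otherwise the base.
base_at <- function(alns, pos) {
  out <- rep(".", nrow(alns))
  covered <- alns$ref_start <= pos & pos < alns$ref_end
  idx <- pos - alns$ref_start[covered] + 1L
  out[covered] <- substring(alns$span[covered], idx, idx)
  out
}
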