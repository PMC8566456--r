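#' Editing specificity with a detection-limit floor on indels
#'
#' Specificity of a base-editing outcome is the on-target base-editing
#' percentage divided by the indel percentage. Because an indel percentage
#' below the resolution limit of amplicon sequencing (0.05%) would inflate
#' the ratio arbitrarily, the denominator is floored at `floor_pct`:
#' `specificity = editing_pct / max(indel_pct, floor_pct)`. The floor
#' applies to the denominator only, never to the editing percentage.
#'
#' @param editing_pct On-target editing percentage(s); `NA` propagates.
#' @param indel_pct Indel percentage(s) from the same sample.
#' @param floor_pct Detection-limit floor in percent (default 0.05).
#' @return A tibble with `editing_pct`, `indel_pct`, `floor_pct`,
#'   `floor_engaged` and `specificity`.
#' @examples
#' specificity(50, 10)      # 5
#' specificity(45, 0.02)    # floored: 45 / 0.05 = 900
#' @export
specificity <- function(editing_pct, indel_pct, floor_pct = 0.05) {
  stopifnot(is.numeric(editing_pct), is.numeric(indel_pct),
            length(floor_pct) == 1, floor_pct > 0)
  if (any(editing_pct < 0, na.rm = TRUE) ||
      any(indel_pct < 0, na.rm = TRUE)) {
    abort("percentages must be non-negative")
  }
  n <- max(length(editing_pct), length(indel_pct))
  editing_pct <- rep_len(editing_pct, n)
  indel_pct <- rep_len(indel_pct, n)
  engaged <- !is.na(indel_pct) & indel_pct < floor_pct
  denom <- pmax(indel_pct, floor_pct)
  tibble(editing_pct = editing_pct, indel_pct = indel_pct,
         floor_pct = floor_pct, floor_engaged = engaged,
         specificity = editing_pct / denom)
}

edit_freq_of <- function(x) {
  if (inherits(x, "quant_result")) x$intended_edit_frequency
  else if (is.numeric(x) && length(x) == 1) x
  else abort("expected a quant_result or a single numeric editing frequency")
}

#' Enrichment fold between two samples
#'
#' Ratio of intended-edit frequencies, enriched over baseline — e.g. the
#' genomic editing rate among reporter-positive sorted cells over the rate
#' without sorting. A zero or undefined baseline yields `NA` (missing),
#' never an infinite fold.
#'
#' @param enriched,baseline `quant_result` objects or single numeric
#'   editing frequencies.
#' @return A single numeric fold, or `NA`.
#' @export
enrichment_fold <- function(enriched, baseline) {
  num <- edit_freq_of(enriched)
  den <- edit_freq_of(baseline)
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  num / den
}

#' Construct an activity profile
#'
#' An activity profile pairs target or sgRNA identifiers with a signal:
#' percent-positive cells from the reporter readout, or editing
#' percentages. `kind` records the scale: `"raw"`, `"normalized_to_active"`
#' (divided by the active-control plasmid signal) or `"off_over_on"`
#' (off-target over matched on-target).
#'
#' @param labels Unique identifiers.
#' @param values Numeric signal values.
#' @param kind One of `"raw"`, `"normalized_to_active"`, `"off_over_on"`.
#' @return A tibble of class `activity_profile` with columns `label`,
#'   `value` and attribute `kind`.
#' @export
activity_profile <- function(labels, values,
                             kind = c("raw", "normalized_to_active",
                                      "off_over_on")) {
  kind <- match.arg(kind)
  if (anyDuplicated(labels)) abort("profile labels must be unique")
  stopifnot(length(labels) == length(values), is.numeric(values))
  structure(tibble(label = as.character(labels), value = as.numeric(values)),
            kind = kind, class = c("activity_profile", "tbl_df", "tbl",
                                   "data.frame"))
}

profile_kind <- function(profile) attr(profile, "kind") %||% "raw"

#' Normalise an activity profile to a reference signal
#'
#' Divides every value by `reference_value`: the active splice-donor
#' control plasmid signal for on-target profiles
#' (`kind = "normalized_to_active"`), or the matched on-target sgRNA signal
#' for mismatch-tolerance profiles (`kind = "off_over_on"`). Normalised
#' values are expected in `[0, 1]`; values above 1 are flagged in the
#' `overshoot` column and a warning is raised when any exceeds 1.05.
#'
#' @param profile An [activity_profile()] or a data frame with `label` and
#'   `value` columns.
#' @param reference_value Positive reference signal.
#' @param kind Kind of the normalised profile.
#' @return An [activity_profile()] with normalised `value` and logical
#'   `overshoot`.
#' @export
normalize_profile <- function(profile, reference_value,
                              kind = c("normalized_to_active",
                                       "off_over_on")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(profile),
            all(c("label", "value") %in% names(profile)))
  if (!is.numeric(reference_value) || length(reference_value) != 1 ||
      is.na(reference_value) || reference_value <= 0) {
    abort("`reference_value` must be a single positive number")
  }
  out <- activity_profile(profile$label, profile$value / reference_value,
                          kind = kind)
  out$overshoot <- !is.na(out$value) & out$value > 1
  if (any(out$value > 1.05, na.rm = TRUE)) {
    warn(sprintf("%d normalised value(s) exceed 1.05",
                 sum(out$value > 1.05, na.rm = TRUE)))
  }
  out
}

#' Pearson correlation between two activity profiles
#'
#' Standard product-moment correlation on paired values, used to compare
#' activity profiles across contexts (e.g. plasmid reporter vs
#' genome-integrated reporter over a shared sgRNA panel). Profiles must
#' carry the same labels in the same order and at least 3 pairs; zero
#' variance in either profile yields `NA` with a warning. The coefficient
#' is invariant under affine rescaling of either profile, so raw and
#' normalised profiles give the same r.
#'
#' @param a,b [activity_profile()]s or data frames with `label`, `value`.
#' @return Pearson's r, or `NA` when undefined.
#' @export
profile_correlation <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(c("label", "value") %in% names(a)),
            all(c("label", "value") %in% names(b)))
  if (nrow(a) != nrow(b) || !all(a$label == b$label)) {
    abort("profiles must share the same labels in the same order")
  }
  if (nrow(a) < 3) abort("need at least 3 paired values")
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0) {
    warn("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(a$value, b$value, method = "pearson")
}

#' Plot an activity profile
#'
#' @param object An [activity_profile()].
#' @param ... Unused.
#' @return A ggplot bar chart of values by label.
#' @importFrom ggplot2 geom_hline
#' @export
autoplot.activity_profile <- function(object, ...) {
  dat <- mutate(as_tibble(object),
                label = factor(.data$label, levels = .data$label))
  p <- ggplot(dat, aes(x = .data$label, y = .data$value)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = profile_kind(object)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (profile_kind(object) != "raw") {
    p <- p + geom_hline(yintercept = 1, linetype = "dashed")
  }
  p
}

complement_rule <- function(bases) comp_base(bases)

#' Default mismatch-block layout for a spacer
#'
#' Blocks of 1-5 consecutive mismatched positions, ten starts per block
#' length spread evenly across the spacer, giving a 50-variant panel in the
#' spirit of mismatch-tolerance screens. The exact positions of any
#' particular published panel are figure-encoded, so the layout is a
#' configurable stand-in, not a reproduction.
#'
#' @param spacer_len Spacer length (default 20).
#' @param lengths Block lengths (default 1:5).
#' @param starts_per_length Number of block starts per length (default 10).
#' @return A tibble with `start` (1-based from the PAM-distal end) and
#'   `length`.
#' @export
default_mismatch_blocks <- function(spacer_len = 20L, lengths = 1:5,
                                    starts_per_length = 10L) {
  purrr::map(lengths, function(L) {
    starts <- unique(round(seq(1, spacer_len - L + 1,
                               length.out = starts_per_length)))
    tibble(start = as.integer(starts), length = as.integer(L))
  }) |> bind_rows()
}

#' Generate a panel of mismatched spacer variants
#'
#' For each block (start, length), substitutes the block's bases according
#' to `substitution_rule` (default: Watson-Crick complement, which
#' guarantees a true mismatch at every block position). Every variant
#' differs from the spacer at exactly its block positions, so its Hamming
#' distance equals the block length.
#'
#' @param spacer The on-target 20-nt spacer (5' to 3', position 1 =
#'   PAM-distal end).
#' @param blocks Data frame with columns `start` (1-based) and `length`
#'   (1-5 typical); default [default_mismatch_blocks()].
#' @param substitution_rule `"complement"` or a function mapping a
#'   character vector of bases to replacement bases (must never return the
#'   input base).
#' @return A tibble of class `mismatch_panel`: `start`, `length`,
#'   `variant`, `hamming`; attribute `spacer`.
#' @export
mismatch_panel <- function(spacer, blocks = default_mismatch_blocks(
                             nchar(spacer)),
                           substitution_rule = "complement") {
  check_dna(spacer, "spacer")
  stopifnot(is.data.frame(blocks),
            all(c("start", "length") %in% names(blocks)))
  L <- nchar(spacer)
  if (any(blocks$start < 1 | blocks$length < 1 |
          blocks$start + blocks$length - 1L > L)) {
    abort("every block must lie fully within the spacer")
  }
  rule <- if (is.function(substitution_rule)) substitution_rule
          else complement_rule
  variants <- purrr::pmap_chr(blocks[c("start", "length")], function(
      start, length) {
    v <- chars(spacer)
    idx <- start:(start + length - 1L)
    repl <- rule(v[idx])
    if (any(repl == v[idx])) {
      abort("substitution rule returned the original base (not a mismatch)")
    }
    v[idx] <- repl
    paste(v, collapse = "")
  })
  out <- tibble(start = as.integer(blocks$start),
                length = as.integer(blocks$length), variant = variants)
  out$hamming <- purrr::map_int(out$variant, function(v) {
    sum(chars(v) != chars(spacer))
  })
  structure(out, spacer = spacer,
            class = c("mismatch_panel", "tbl_df", "tbl", "data.frame"))
}
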