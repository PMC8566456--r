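#' Prefix identity of an aligned read
#'
#' Fraction of the first `prefix_len` reference positions that the read
#' aligns as exact matches. Substitutions, deletions, `N` bases and prefix
#' positions the alignment does not reach all count as non-matches, so a
#' read starting deep inside the amplicon scores low even if it is
#' error-free. This is the quantity behind the read-retention rule
#' (at least 75% identity over the first 20 reference bases).
#'
#' @param aln A `read_alignment` from [align_semi_global()].
#' @param prefix_len Number of leading reference positions considered
#'   (default 20).
#' @return A fraction in `[0, 1]`.
#' @export
prefix_identity <- function(aln, prefix_len = 20L) {
  stopifnot(inherits(aln, "read_alignment"))
  prefix_len <- as.integer(prefix_len)
  if (prefix_len <= 0L || prefix_len > nchar(aln$reference)) {
    abort("`prefix_len` must be in [1, reference length]")
  }
  tbl <- aln_tbl_from_object(aln)
  prefix_identity_batch(tbl, aln$reference, prefix_len)
}

# vectorised prefix identity over an align_batch() tibble
prefix_identity_batch <- function(alns, reference, prefix_len) {
  n <- nrow(alns)
  matched <- integer(n)
  lo <- pmax(alns$ref_start, 0L)
  hi <- pmin(alns$ref_end, prefix_len)
  idx <- which(lo < hi)
  matched[idx] <- purrr::map_int(idx, function(i) {
    s <- substring(alns$span[i], lo[i] - alns$ref_start[i] + 1L,
                   hi[i] - alns$ref_start[i])
    r <- substring(reference, lo[i] + 1L, hi[i])
    sc <- chars(s)
    sum(sc == chars(r) & sc != "N")
  })
  matched / prefix_len
}

normalize_reads <- function(reads) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%06d", seq_along(reads)),
                    seq = reads)
  }
  reads <- as_tibble(reads)
  stopifnot("seq" %in% names(reads))
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))
  }
  reads
}

#' Retain reads by prefix identity to the reference
#'
#' Aligns each read to the reference amplicon and keeps those whose
#' [prefix_identity()] over the first `prefix_len` reference positions is at
#' least `threshold` (defaults: 0.75 over 20 bp). Counts are conserved:
#' every input read lands in exactly one of the two output tables.
#'
#' @param reads A data frame with columns `seq` (and optionally `read_id`),
#'   or a character vector of read sequences.
#' @param reference Reference amplicon (DNA string).
#' @param threshold Minimum prefix identity for retention (default 0.75).
#' @param prefix_len Prefix length in reference bases (default 20).
#' @param scoring An [align_scoring()] object.
#' @param auto_orient Align the reverse complement as well and keep the
#'   better orientation when it wins by at least `|gap_open|`.
#' @return A list with tibbles `retained` and `filtered_out`, each carrying
#'   `read_id`, `seq` and `prefix_identity`.
#' @export
filter_reads <- function(reads, reference, threshold = 0.75,
                         prefix_len = 20L, scoring = align_scoring(),
                         auto_orient = TRUE) {
  reads <- normalize_reads(reads)
  if (nrow(reads) == 0) {
    empty <- mutate(reads, prefix_identity = numeric(0))
    return(list(retained = empty, filtered_out = empty))
  }
  alns <- align_batch(reads$seq, reference, scoring,
                      read_ids = reads$read_id, auto_orient = auto_orient)
  pid <- prefix_identity_batch(alns, reference, as.integer(prefix_len))
  out <- mutate(reads, prefix_identity = pid)
  list(retained = out[pid >= threshold, , drop = FALSE],
       filtered_out = out[pid < threshold, , drop = FALSE])
}

aln_tbl_from_object <- function(aln) {
  a <- chars(aln$ref_aln)
  b <- chars(aln$read_aln)
  tibble(read_id = aln$read_id, seq = aln$read, orientation = "+",
         score = aln$score, ref_start = aln$ref_start,
         ref_end = aln$ref_end, ref_aln = aln$ref_aln,
         read_aln = aln$read_aln,
         span = paste(b[a != "-"], collapse = ""))
}

# Per-read gap and substitution features needed by the indel caller.
read_features <- function(alns, reference) {
  purrr::pmap(alns[c("span", "ref_start", "ref_aln")], function(
      span, ref_start, ref_aln) {
    sc <- chars(span)
    rc <- chars(substring(reference, ref_start + 1L,
                          ref_start + length(sc)))
    is_del <- sc == "-"
    sub_pos <- ref_start + which(!is_del & sc != rc) - 1L
    dels <- NULL
    if (any(is_del)) {
      r <- rle(is_del)
      e <- cumsum(r$lengths)
      s <- e - r$lengths + 1L
      keep <- r$values
      dels <- cbind(start = ref_start + s[keep] - 1L,
                    end = ref_start + e[keep])  # 0-based half-open
    }
    ins <- NULL
    if (grepl("-", ref_aln, fixed = TRUE)) {
      a <- chars(ref_aln)
      before <- ref_start + c(0L, cumsum(a != "-"))[seq_along(a)]
      ins <- unique(before[a == "-"])
    }
    list(sub_pos = sub_pos, dels = dels, ins = ins)
  })
}

# Core caller on an align_batch() tibble of *retained* reads.
call_reads_impl <- function(alns, site, window_halfwidth = 2L,
                            strict_flanks = TRUE) {
  n <- nrow(alns)
  ed <- site$editable_positions
  npos <- nrow(ed)
  feats <- read_features(alns, site$reference)
  wlo <- site$cut_site - as.integer(window_halfwidth)
  whi <- site$cut_site + as.integer(window_halfwidth)
  obs <- matrix(".", nrow = n, ncol = npos)
  if (npos > 0) {
    for (k in seq_len(npos)) obs[, k] <- base_at(alns, ed$position[k])
  }
  status <- character(n)
  covers <- logical(n)
  conversions <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    gap_hit <- FALSE
    if (!is.null(f$dels) && nrow(f$dels) > 0) {
      gap_hit <- any(f$dels[, "start"] <= whi & f$dels[, "end"] - 1L >= wlo)
    }
    if (!gap_hit && !is.null(f$ins)) {
      gap_hit <- any(f$ins >= wlo & f$ins <= whi)
    }
    o <- if (npos > 0) obs[i, ] else character(0)
    covers[i] <- all(o != ".")
    hit <- o == ed$to
    is_conv <- !(o %in% c(".", "-", "N")) & o != ed$from
    clean_subs <- length(setdiff(f$sub_pos, ed$position)) == 0L
    if (gap_hit && (!strict_flanks || clean_subs)) {
      status[i] <- "indel"
    } else if (any(is_conv & o != ed$to)) {
      status[i] <- "byproduct"
    } else if (npos > 0 && all(hit)) {
      status[i] <- "edited"
    } else if (any(hit)) {
      status[i] <- "partially_edited"
    } else {
      status[i] <- "unedited"
    }
    cv <- which(is_conv)
    conversions[[i]] <- if (length(cv)) {
      tibble(position = ed$position[cv], from = ed$from[cv], to = o[cv])
    } else {
      tibble(position = integer(), from = character(), to = character())
    }
  }
  tibble(read_id = alns$read_id, status = status, covers_target = covers,
         conversions = conversions)
}

#' Call the editing outcome of one aligned read
#'
#' Classifies a retained read as `indel`, `edited`, `partially_edited`,
#' `byproduct` or `unedited` against a [target_site()]. A read is an indel
#' read when some gap run's reference footprint intersects the closed
#' window `cut_site` +/- `window_halfwidth` (a deletion by reference
#' overlap, an insertion by its anchoring reference coordinate), with any
#' gap size allowed; under `strict_flanks` (the "indels without mismatches"
#' rule) a gap-bearing read only qualifies if it carries no substitutions
#' outside the designated editable positions. Otherwise the read is
#' classified from the bases observed at the editable positions: `edited`
#' when every position shows its expected product, `byproduct` when any
#' position shows an unexpected conversion (e.g. the C-to-G minority
#' outcome of cytosine editing), `partially_edited` when only some expected
#' conversions are present, `unedited` otherwise. `N` never counts as a
#' conversion.
#'
#' @param aln A `read_alignment`.
#' @param site A [target_site()].
#' @param window_halfwidth Half-width of the cut-site indel window in bases
#'   (default 2).
#' @param strict_flanks Require indel reads to be substitution-free outside
#'   the editable positions (default `TRUE`).
#' @return A one-row tibble: `read_id`, `status`, `covers_target`, and a
#'   `conversions` list column of (position, from, to).
#' @export
call_read <- function(aln, site, window_halfwidth = 2L,
                      strict_flanks = TRUE) {
  stopifnot(inherits(aln, "read_alignment"), inherits(site, "target_site"))
  call_reads_impl(aln_tbl_from_object(aln), site,
                  window_halfwidth = window_halfwidth,
                  strict_flanks = strict_flanks)
}

#' Quantify base-editing outcomes from amplicon reads
#'
#' Full quantification pipeline: semi-global alignment of each read to the
#' reference amplicon, retention of reads matching at least
#' `identity_threshold` over the first `prefix_len` reference bases, indel
#' calling in the `cut_site` +/- `window_halfwidth` window, outcome
#' classification at the designated editable positions, and a per-position
#' base-conversion matrix over the protospacer +/- `flank` bases.
#'
#' Frequencies follow the amplicon-sequencing conventions: `indel_frequency`
#' is (reads with an indel) / (retained reads), and
#' `intended_edit_frequency` is (retained reads with every editable position
#' converted to its expected product) / (retained reads covering all
#' editable positions). Zero denominators yield `NA`, never 0.
#'
#' @inheritParams filter_reads
#' @inheritParams call_read
#' @param site A [target_site()]; its `reference` is the alignment target.
#' @param flank Flank (in bases) around the protospacer covered by the
#'   conversion matrix (default 10).
#' @return A `quant_result` object; see [glance.quant_result()] for the
#'   one-row summary and [tidy.quant_result()] for the per-position
#'   conversion matrix.
#' @examples
#' site <- target_site(paste0(strrep("A", 12), "TACGTGAGTACGATCGAC",
#'                            "AGGCCTT"), proto_start = 10, check_pam = FALSE)
#' q <- quantify(c(site$reference, site$reference), site)
#' glance(q)
#' @export
quantify <- function(reads, site, identity_threshold = 0.75,
                     prefix_len = 20L, window_halfwidth = 2L,
                     strict_flanks = TRUE, flank = 10L,
                     scoring = align_scoring(), auto_orient = TRUE) {
  stopifnot(inherits(site, "target_site"))
  reads <- normalize_reads(reads)
  params <- list(identity_threshold = identity_threshold,
                 prefix_len = as.integer(prefix_len),
                 window_halfwidth = as.integer(window_halfwidth),
                 strict_flanks = strict_flanks, flank = as.integer(flank),
                 scoring = unclass(scoring), auto_orient = auto_orient)
  n_total <- nrow(reads)
  if (n_total == 0) {
    return(new_quant_result(0L, 0L, 0L, 0L, site, params,
                            calls = NULL, alns = NULL))
  }
  alns <- align_batch(reads$seq, site$reference, scoring,
                      read_ids = reads$read_id, auto_orient = auto_orient)
  pid <- prefix_identity_batch(alns, site$reference,
                               as.integer(prefix_len))
  keep <- pid >= identity_threshold
  ret <- alns[keep, , drop = FALSE]
  calls <- if (nrow(ret)) {
    call_reads_impl(ret, site, window_halfwidth, strict_flanks)
  } else {
    NULL
  }
  new_quant_result(n_total, sum(keep), sum(!keep),
                   if (is.null(calls)) 0L else sum(calls$status == "indel"),
                   site, params, calls = calls, alns = ret)
}

new_quant_result <- function(n_total, n_retained, n_filtered, n_indel, site,
                             params, calls, alns) {
  npos <- nrow(site$editable_positions)
  if (is.null(calls)) {
    calls <- tibble(read_id = character(), status = character(),
                    covers_target = logical(), conversions = list())
  }
  n_covering <- sum(calls$covers_target)
  n_edited <- sum(calls$status == "edited")
  intended <- if (npos == 0) NA_real_ else safe_div(n_edited, n_covering)
  per_editable <- editable_summary(site, calls, alns)
  conv <- if (!is.null(alns) && nrow(alns)) {
    conversion_matrix_impl(alns, site, params$flank)
  } else {
    empty_conversion_matrix()
  }
  structure(list(n_total = as.integer(n_total),
                 n_retained = as.integer(n_retained),
                 n_filtered = as.integer(n_filtered),
                 n_indel = as.integer(n_indel),
                 indel_frequency = safe_div(n_indel, n_retained),
                 n_covering = as.integer(n_covering),
                 intended_edit_frequency = intended,
                 per_editable = per_editable, conversion = conv,
                 calls = calls, site = site, params = params),
            class = "quant_result")
}

editable_summary <- function(site, calls, alns) {
  ed <- site$editable_positions
  if (nrow(ed) == 0 || is.null(alns) || nrow(alns) == 0) {
    return(mutate(ed, n_covering = integer(nrow(ed)),
                  n_expected = integer(nrow(ed)),
                  frac_expected = numeric(nrow(ed)),
                  n_byproduct = integer(nrow(ed)),
                  frac_byproduct = numeric(nrow(ed))))
  }
  purrr::pmap(ed, function(position, from, to) {
    o <- base_at(alns, position)
    covering <- !(o %in% c(".", "-"))
    nc <- sum(covering)
    nexp <- sum(o == to)
    nby <- sum(covering & o != from & o != to & o != "N")
    tibble(position = position, from = from, to = to, n_covering = nc,
           n_expected = nexp, frac_expected = safe_div(nexp, nc),
           n_byproduct = nby, frac_byproduct = safe_div(nby, nc))
  }) |> bind_rows()
}

empty_conversion_matrix <- function() {
  tibble(position = integer(), ref_base = character(), base = character(),
         count = integer(), n_covering = integer(), fraction = numeric())
}

conversion_matrix_impl <- function(alns, site, flank) {
  lo <- max(site$proto_start - flank, 0L)
  hi <- min(site$proto_end + flank, nchar(site$reference))
  positions <- seq.int(lo, hi - 1L)
  cats <- c(DNA_BASES, "del", "other")
  purrr::map(positions, function(p) {
    o <- base_at(alns, p)
    o <- o[o != "."]
    lab <- ifelse(o == "-", "del", ifelse(o %in% DNA_BASES, o, "other"))
    cnt <- table(factor(lab, levels = cats))
    tibble(position = p,
           ref_base = substring(site$reference, p + 1L, p + 1L),
           base = cats, count = as.integer(cnt), n_covering = length(o),
           fraction = safe_div(as.integer(cnt), length(o)))
  }) |> bind_rows()
}

#' Per-position base-conversion matrix
#'
#' For every reference coordinate in the protospacer +/- `flank` bases,
#' counts the base observed (A/C/G/T, `del` for a deleted position, `other`
#' for `N`) among retained reads covering that coordinate. Intended targets
#' and bystander positions stand out as columns with elevated non-reference
#' fractions.
#'
#' @inheritParams quantify
#' @return A long tibble: `position` (0-based), `ref_base`, `base`, `count`,
#'   `n_covering`, `fraction`. For each position the counts sum to the
#'   number of retained reads covering it.
#' @export
conversion_matrix <- function(reads, site, flank = 10L,
                              identity_threshold = 0.75, prefix_len = 20L,
                              scoring = align_scoring(),
                              auto_orient = TRUE) {
  stopifnot(inherits(site, "target_site"))
  reads <- normalize_reads(reads)
  if (nrow(reads) == 0) return(empty_conversion_matrix())
  alns <- align_batch(reads$seq, site$reference, scoring,
                      read_ids = reads$read_id, auto_orient = auto_orient)
  pid <- prefix_identity_batch(alns, site$reference, as.integer(prefix_len))
  ret <- alns[pid >= identity_threshold, , drop = FALSE]
  if (nrow(ret) == 0) return(empty_conversion_matrix())
  conversion_matrix_impl(ret, site, as.integer(flank))
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(paste0("<quant_result> %d reads: %d retained, %d filtered, ",
                     "%d indel\n"), x$n_total, x$n_retained, x$n_filtered,
              x$n_indel))
  cat(sprintf("  indel frequency: %s\n  intended edit frequency: %s\n",
              format(x$indel_frequency), format(x$intended_edit_frequency)))
  invisible(x)
}

#' One-row summary of a quantification result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return A one-row tibble with the counts and frequencies. Undefined
#'   frequencies (zero denominators) are `NA`.
#' @export
glance.quant_result <- function(x, ...) {
  tibble(n_total = x$n_total, n_retained = x$n_retained,
         n_filtered = x$n_filtered, n_indel = x$n_indel,
         n_covering = x$n_covering,
         indel_frequency = x$indel_frequency,
         intended_edit_frequency = x$intended_edit_frequency)
}

#' Per-position conversion matrix of a quantification result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return The long-format conversion matrix tibble (see
#'   [conversion_matrix()]).
#' @export
tidy.quant_result <- function(x, ...) {
  x$conversion
}

#' Plot the per-position non-reference base fractions
#'
#' Stacked per-position fractions of non-reference bases (conversions and
#' deletions) across the protospacer and its flanks; the protospacer span
#' is shaded and the cut site marked.
#'
#' @param object A `quant_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_vline annotate labs
#'   scale_fill_brewer theme_minimal
#' @export
autoplot.quant_result <- function(object, ...) {
  dat <- filter(object$conversion, .data$base != .data$ref_base,
                .data$count > 0)
  p <- ggplot(dat, aes(x = .data$position, y = .data$fraction,
                       fill = .data$base)) +
    annotate("rect", xmin = object$site$proto_start - 0.5,
             xmax = object$site$proto_end - 0.5, ymin = -Inf, ymax = Inf,
             alpha = 0.08) +
    geom_col() +
    geom_vline(xintercept = object$site$cut_site, linetype = "dashed") +
    scale_fill_brewer(palette = "Set1") +
    labs(x = "reference position (0-based)",
         y = "fraction of covering reads", fill = "observed") +
    theme_minimal()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
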