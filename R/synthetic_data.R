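default_indel_sizes <- function() {
  c(`-3` = 0.10, `-2` = 0.15, `-1` = 0.40, `1` = 0.25, `2` = 0.10)
}

#' Ground truth for a simulated amplicon sample
#'
#' Bundles the generative parameters of one simulated deep-sequencing
#' sample: the intended-edit rate, per-position bystander rates, the
#' C-to-G byproduct fraction among edited cytosines, the cut-site indel
#' rate with its size distribution, the uniform per-base substitution
#' sequencing-error rate, the read count and the mandatory seed. There is
#' no hidden global randomness: identical truth (including the seed) gives
#' byte-identical reads.
#'
#' @param editing_rate Probability a non-indel read carries the intended
#'   conversion(s) (default 0.3, a mid-range unenriched editing level).
#' @param bystander_rates Optional data frame with columns `position`
#'   (0-based reference coordinate) and `rate`; each position is converted
#'   independently at its rate with the deamination-style product of its
#'   reference base (A to G, C to T, G to A, T to C).
#' @param byproduct_fraction Fraction of edited cytosines resolving to G
#'   instead of T (default 0.1); only engages for C-to-T editable
#'   positions.
#' @param indel_rate Probability a read carries one cut-site indel
#'   (default 0.01).
#' @param indel_size_probs Named numeric vector mapping signed indel sizes
#'   (negative = deletion) to probabilities; must sum to 1.
#' @param error_rate Per-base substitution sequencing-error rate
#'   (default 0.001).
#' @param n_reads Number of reads (default 10000).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(editing_rate = 0.3, bystander_rates = NULL,
                      byproduct_fraction = 0.1, indel_rate = 0.01,
                      indel_size_probs = default_indel_sizes(),
                      error_rate = 0.001, n_reads = 10000L, seed) {
  if (missing(seed)) abort("`seed` is mandatory for sim_truth()")
  probs <- c(editing_rate, byproduct_fraction, indel_rate, error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all rates must lie in [0, 1]")
  }
  if (is.null(bystander_rates)) {
    bystander_rates <- tibble(position = integer(), rate = numeric())
  } else {
    bystander_rates <- as_tibble(bystander_rates)
    stopifnot(all(c("position", "rate") %in% names(bystander_rates)))
    if (any(bystander_rates$rate < 0 | bystander_rates$rate > 1)) {
      abort("bystander rates must lie in [0, 1]")
    }
  }
  sizes <- as.integer(names(indel_size_probs))
  if (anyNA(sizes) || any(sizes == 0L) ||
      abs(sum(indel_size_probs) - 1) > 1e-8) {
    abort("`indel_size_probs` needs non-zero signed sizes summing to 1")
  }
  structure(list(editing_rate = editing_rate,
                 bystander_rates = bystander_rates,
                 byproduct_fraction = byproduct_fraction,
                 indel_rate = indel_rate,
                 indel_size_probs = indel_size_probs,
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 seed = as.integer(seed)),
            class = "sim_truth")
}

deamination_product <- c(A = "G", C = "T", G = "A", T = "C")

# Canonical (left-aligned) placement of a deletion of k reference bases at
# 0-based anchor a: shift left while the base entering equals the one
# leaving, mirroring the aligner's gap canonicalisation.
left_shift_deletion <- function(ref_chars, a, k) {
  while (a > 0 && ref_chars[a] == ref_chars[a + k]) a <- a - 1L
  a
}

left_shift_insertion <- function(ref_chars, a, ins) {
  k <- length(ins)
  while (a > 0 && ref_chars[a] == ins[k]) {
    ins <- c(ref_chars[a], ins[-k])
    a <- a - 1L
  }
  list(anchor = a, ins = ins)
}

#' Simulate amplicon reads with known editing outcomes
#'
#' Generates single-end reads spanning the reference amplicon of a
#' [target_site()]. Independently per read: with probability `indel_rate`
#' the read carries one indel of sampled signed size whose canonical
#' (left-aligned) footprint intersects the +/-2 bp cut-site window
#' (deletions by reference overlap, insertions by anchor coordinate;
#' placement uniform over valid anchors, resampled if left-alignment
#' shifts the footprint out of the window); otherwise, with probability
#' `editing_rate` the read carries the intended conversion at every
#' editable position, each edited C independently redirected to G with
#' probability `byproduct_fraction`, and bystander conversions are applied
#' independently per position. Uniform substitution errors at `error_rate`
#' are layered over every read (indel reads included); sequencing indel
#' errors are deliberately excluded so the indel caller's truth is
#' unambiguous.
#'
#' @param site A [target_site()].
#' @param truth A [sim_truth()].
#' @return A list with `reads` (tibble `read_id`, `seq`, `qual`) and the
#'   echoed `truth`.
#' @export
simulate_reads <- function(site, truth) {
  stopifnot(inherits(site, "target_site"), inherits(truth, "sim_truth"))
  ref <- site$reference
  len <- nchar(ref)
  rc <- chars(ref)
  ed <- site$editable_positions
  by <- truth$bystander_rates
  if (nrow(by)) {
    if (any(by$position < 0 | by$position >= len)) {
      abort("bystander positions fall outside the reference")
    }
    if (any(by$position %in% ed$position)) {
      abort("bystander positions overlap the designated editable positions")
    }
  }
  wlo <- site$cut_site - 2L
  whi <- site$cut_site + 2L
  withr::with_seed(truth$seed, {
    n <- truth$n_reads
    is_indel <- runif(n) < truth$indel_rate
    seqs <- character(n)

    # --- substitution-class reads, vectorised over a char matrix ---
    m <- sum(!is_indel)
    if (m > 0) {
      mat <- matrix(rc, nrow = m, ncol = len, byrow = TRUE)
      edited <- runif(m) < truth$editing_rate
      if (nrow(ed) > 0 && any(edited)) {
        for (k in seq_len(nrow(ed))) {
          j <- ed$position[k] + 1L
          product <- rep(ed$to[k], sum(edited))
          if (ed$from[k] == "C" && ed$to[k] == "T" &&
              truth$byproduct_fraction > 0) {
            redirect <- runif(sum(edited)) < truth$byproduct_fraction
            product[redirect] <- "G"
          }
          mat[edited, j] <- product
        }
      }
      if (nrow(by) > 0) {
        for (k in seq_len(nrow(by))) {
          j <- by$position[k] + 1L
          hitby <- runif(m) < by$rate[k]
          mat[hitby, j] <- deamination_product[[rc[j]]]
        }
      }
      if (truth$error_rate > 0) {
        err <- which(matrix(runif(m * len) < truth$error_rate, m, len))
        if (length(err)) {
          cur <- mat[err]
          pick <- ceiling(runif(length(err)) * 3)
          mat[err] <- vapply(seq_along(err), function(i) {
            setdiff(DNA_BASES, cur[i])[pick[i]]
          }, character(1))
        }
      }
      seqs[!is_indel] <- do.call(paste0, as.data.frame(mat,
                                                       optional = TRUE))
    }

    # --- indel reads, one at a time ---
    idx_indel <- which(is_indel)
    if (length(idx_indel)) {
      sizes <- as.integer(names(truth$indel_size_probs))
      drawn <- sample(sizes, length(idx_indel), replace = TRUE,
                      prob = truth$indel_size_probs)
      for (t in seq_along(idx_indel)) {
        s <- drawn[t]
        if (s < 0) {  # deletion of k bases
          k <- -s
          lo <- max(0L, wlo - k + 1L)
          hi <- min(len - k, whi)
          if (lo > hi) abort("no valid deletion anchor for this site")
          repeat {
            a <- lo + floor(runif(1) * (hi - lo + 1L))
            a2 <- left_shift_deletion(rc, a, k)
            if (a2 <= whi && a2 + k - 1L >= wlo) break
          }
          read <- paste0(substr(ref, 1L, a2), substr(ref, a2 + k + 1L, len))
        } else {      # insertion of k bases
          k <- s
          repeat {
            a <- max(0L, wlo) + floor(runif(1) * (min(len, whi) -
                                                    max(0L, wlo) + 1L))
            ins <- DNA_BASES[ceiling(runif(k) * 4)]
            can <- left_shift_insertion(rc, a, ins)
            if (can$anchor >= wlo && can$anchor <= whi) break
          }
          read <- paste0(substr(ref, 1L, can$anchor),
                         paste(can$ins, collapse = ""),
                         substr(ref, can$anchor + 1L, len))
        }
        if (truth$error_rate > 0) {
          v <- chars(read)
          err <- which(runif(length(v)) < truth$error_rate)
          for (i in err) {
            v[i] <- setdiff(DNA_BASES, v[i])[ceiling(runif(1) * 3)]
          }
          read <- paste(v, collapse = "")
        }
        seqs[idx_indel[t]] <- read
      }
    }

    reads <- tibble(read_id = sprintf("read%06d", seq_len(n)), seq = seqs,
                    qual = strrep("I", nchar(seqs)))
    list(reads = reads, truth = truth)
  })
}

#' Ground truth for a simulated sorted cell population
#'
#' The shared-competence model behind reporter-based enrichment: within
#' transfected cells a latent competent fraction `competent_fraction`
#' (cells in which the editor is expressed and active) edits the reporter
#' with probability `reporter_edit_prob` and the genomic target with
#' probability `genomic_edit_prob`, independently given competence.
#' Non-competent and untransfected cells edit nothing. The expected
#' unsorted genomic edit rate is `transfected_fraction * competent_fraction
#' * genomic_edit_prob` in closed form, and with `reporter_edit_prob = 1`
#' the reporter-gated over transfection-gated enrichment fold is exactly
#' `1 / competent_fraction`. The model is a fixture reproducing the
#' qualitative structure of reporter enrichment, not a biological claim.
#'
#' @param n_cells Number of cells (default 100000).
#' @param competent_fraction Latent competent fraction among transfected
#'   cells (default 0.5).
#' @param reporter_edit_prob Reporter edit probability in competent cells
#'   (default 0.8).
#' @param genomic_edit_prob Genomic edit probability in competent cells
#'   (default 0.6).
#' @param transfected_fraction Transfected fraction of all cells
#'   (default 0.7).
#' @param seed Mandatory integer seed.
#' @return A list of class `population_truth`.
#' @export
population_truth <- function(n_cells = 100000L, competent_fraction = 0.5,
                             reporter_edit_prob = 0.8,
                             genomic_edit_prob = 0.6,
                             transfected_fraction = 0.7, seed) {
  if (missing(seed)) abort("`seed` is mandatory for population_truth()")
  probs <- c(competent_fraction, reporter_edit_prob, genomic_edit_prob,
             transfected_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  structure(list(n_cells = as.integer(n_cells),
                 competent_fraction = competent_fraction,
                 reporter_edit_prob = reporter_edit_prob,
                 genomic_edit_prob = genomic_edit_prob,
                 transfected_fraction = transfected_fraction,
                 seed = as.integer(seed)),
            class = "population_truth")
}

#' Simulate reporter-based enrichment of edited cells
#'
#' Draws a cell population under the shared-competence model of
#' [population_truth()] and reports the genomic edit rate in the three
#' sorting gates used in enrichment experiments: all cells
#' (`no_enrichment`), transfection-marker-positive cells (`transfection`),
#' and reporter-positive cells (`reporter`).
#'
#' @param pop A [population_truth()].
#' @return A list with `cells` (one row per cell: `transfected`,
#'   `competent`, `reporter_edited`, `genome_edited`) and `summary`
#'   (per-gate `n_cells`, `n_edited`, `edit_rate`; `edit_rate` is `NA`
#'   for an empty gate).
#' @export
simulate_enrichment <- function(pop) {
  stopifnot(inherits(pop, "population_truth"))
  withr::with_seed(pop$seed, {
    n <- pop$n_cells
    transfected <- runif(n) < pop$transfected_fraction
    competent <- transfected & runif(n) < pop$competent_fraction
    reporter <- competent & runif(n) < pop$reporter_edit_prob
    genome <- competent & runif(n) < pop$genomic_edit_prob
    cells <- tibble(cell_id = seq_len(n), transfected = transfected,
                    competent = competent, reporter_edited = reporter,
                    genome_edited = genome)
    gates <- list(no_enrichment = rep(TRUE, n), transfection = transfected,
                  reporter = reporter)
    summary <- purrr::imap(gates, function(g, nm) {
      tibble(fraction = nm, n_cells = sum(g), n_edited = sum(genome & g),
             edit_rate = safe_div(sum(genome & g), sum(g)))
    }) |> bind_rows()
    list(cells = cells, summary = summary)
  })
}

#' Simulate a percent-positive flow-cytometry readout
#'
#' Binomial stand-in for a gated percent-positive fluorescence value:
#' `Binomial(n_cells, editing_rate) / n_cells * 100`.
#'
#' @param editing_rate True positive fraction in `[0, 1]`.
#' @param n_cells Number of cells measured (> 0).
#' @param seed Mandatory integer seed.
#' @return A single percentage.
#' @export
simulate_fluorescence <- function(editing_rate, n_cells, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells <= 0) {
    abort("`n_cells` must be a positive count")
  }
  stopifnot(editing_rate >= 0, editing_rate <= 1)
  withr::with_seed(as.integer(seed), {
    rbinom(1, as.integer(n_cells), editing_rate) / n_cells * 100
  })
}
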