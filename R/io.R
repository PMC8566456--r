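fastq_compress <- function(path) {
  if (endsWith(path, ".gz")) "gzip" else FALSE
}

# Structural check of a FASTQ file that reports the offending line number;
# run when the Biostrings parser rejects a file, to say *where* it broke.
validate_fastq_lines <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    if (!startsWith(lines[i], "@")) {
      abort(sprintf("malformed FASTQ record: line %d does not start with '@'",
                    i))
    }
    if (i + 3L > n) {
      abort(sprintf("truncated FASTQ record starting at line %d", i))
    }
    if (!startsWith(lines[i + 2L], "+")) {
      abort(sprintf("malformed FASTQ record: line %d does not start with '+'",
                    i + 2L))
    }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      abort(sprintf(
        "malformed FASTQ record: quality at line %d does not match sequence length",
        i + 3L))
    }
    i <- i + 4L
  }
  invisible(TRUE)
}

#' Read a FASTQ file into a tibble
#'
#' Gzip-transparent by file extension. Malformed files raise an error
#' naming the offending line.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  validate_fastq_lines(path)  # aborts with a line number if malformed
  res <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # names stored as metadata columns are re-attached by Biostrings
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = unname(names(res)) %||%
           sprintf("read%06d", seq_along(res)),
         seq = unname(as.character(res)),
         qual = unname(as.character(Biostrings::quality(res))))
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with `read_id`, `seq` and optionally `qual`
#'   (defaults to Phred 40, "I").
#' @param path Output path; `.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_tibble(reads)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = fastq_compress(path))
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' Wrapped sequence lines are concatenated; gzip-transparent.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = unname(names(x)), seq = unname(as.character(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector, or data frame with `id` and `seq`.
#' @param path Output path; `.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, compress = fastq_compress(path))
  invisible(path)
}

#' Serialise a target site to a JSON config file
#'
#' @param site A [target_site()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_config <- function(site, path) {
  stopifnot(inherits(site, "target_site"))
  cfg <- list(reference = site$reference, proto_start = site$proto_start,
              strand = site$strand, protospacer_len = site$protospacer_len,
              editable_positions = site$editable_positions,
              editing_window = site$editing_window)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a target site from a JSON config file
#'
#' The config holds `reference` (inline DNA string) or `reference_fasta`
#' (path, first record used), plus `proto_start`, `strand`,
#' `protospacer_len`, `editable_positions` and `editing_window` as accepted
#' by [target_site()].
#'
#' @param path Path to the JSON config.
#' @param reference Optional reference sequence overriding the config.
#' @return A [target_site()].
#' @export
read_site_config <- function(path, reference = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- reference %||% cfg$reference %||%
    read_fasta(cfg$reference_fasta)$seq[1]
  ed <- cfg$editable_positions
  if (!is.null(ed) && length(ed) && !is.data.frame(ed)) {
    ed <- bind_rows(ed)
  }
  if (is.data.frame(ed) && nrow(ed) == 0) ed <- NULL
  target_site(ref, cfg$proto_start,
              strand = cfg$strand %||% "+",
              protospacer_len = cfg$protospacer_len %||% 20L,
              editable_positions = ed,
              editing_window = cfg$editing_window %||% c(4L, 8L),
              check_pam = cfg$check_pam %||% TRUE)
}

#' Resolve and record a run configuration
#'
#' Every pipeline run writes its fully resolved parameters (plus the
#' package version) next to its outputs so the run can be reproduced.
#'
#' @param subcommand Name of the pipeline stage.
#' @param params Named list of resolved parameters.
#' @param inputs,outputs Named lists of paths.
#' @return A list of class `run_config`.
#' @export
run_config <- function(subcommand, params = list(), inputs = list(),
                       outputs = list()) {
  structure(list(subcommand = subcommand,
                 version = as.character(utils::packageVersion("bearkit")),
                 params = params, inputs = inputs, outputs = outputs),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param dir Directory in which to write `run_config.json`.
#' @export
write_run_config <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  path <- file.path(dir, "run_config.json")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
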