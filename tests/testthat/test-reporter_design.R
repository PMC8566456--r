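test_that("splice-donor classification follows the mutational-scan rule", {
  # canonical junction and its reported variants
  expect_equal(classify_splice_donor("GT", flank5 = "G", flank3 = "AAGT"),
               "active")
  expect_equal(classify_splice_donor("AC"), "inactive")
  expect_equal(classify_splice_donor("GC"), "active")
  expect_equal(classify_splice_donor("AT"), "active")
  # canonical donor fails when both flanks are altered
  expect_equal(classify_splice_donor("GT", flank5 = "C", flank3 = "CCCC"),
               "inactive")
  # one donor change plus one altered flank is inactive
  expect_equal(classify_splice_donor("AT", flank5 = "C"), "inactive")
  expect_equal(classify_splice_donor("AT", flank3 = "CCCC"), "inactive")
  # the rule only reads the flank canonical status, not which R base
  expect_equal(classify_splice_donor("GT", flank3 = "GAGT"), "active")
  expect_error(classify_splice_donor("GX"), "non-DNA")
  expect_error(classify_splice_donor("G"), "length 2")
})

test_that("donor context table flags canonical flanks and classifies", {
  ctx <- splice_donor_context(c("GT", "AC"), flank5 = c("G", "G"),
                              flank3 = c("AAGT", "TAGT"))
  expect_true(ctx$flank5_canonical[1])
  expect_true(ctx$flank3_canonical[1])
  expect_false(ctx$flank3_canonical[2])  # T is not R
  expect_equal(ctx$class, c("active", "inactive"))
  expect_equal(classify_splice_donor(ctx), ctx$class)
})

test_that("with canonical flanks exactly 7 of 16 donors are active", {
  donors <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  cls <- classify_splice_donor(donors)
  expect_length(donors, 16L)
  expect_equal(sum(cls == "active"), 7L)
  expect_equal(sum(cls == "inactive"), 9L)
  # the active set is GT plus its six single-base variants
  hd <- (substr(donors, 1, 1) != "G") + (substr(donors, 2, 2) != "T")
  expect_setequal(donors[cls == "active"], donors[hd <= 1])
})

test_that("apply_base_edit converts substrate bases and reports skips", {
  expect_equal(as.character(apply_base_edit("AC", "ABE", 0)), "GC")
  expect_equal(as.character(apply_base_edit("AC", "CBE", 1)), "AT")
  expect_equal(as.character(apply_base_edit("ACGT", "CBE_byproduct", 1)),
               "AGGT")
  res <- apply_base_edit("GGGG", "ABE", c(0, 1))
  expect_equal(as.character(res), "GGGG")
  expect_equal(attr(res, "skipped"), c(0L, 1L))
  # idempotent for fixed positions: converted bases are no longer substrate
  once <- apply_base_edit("AACA", "ABE", c(0, 2))
  twice <- apply_base_edit(as.character(once), "ABE", c(0, 2))
  expect_equal(as.character(twice), as.character(once))
  expect_error(apply_base_edit("AC", "ABE", 5), "0-based")
})

test_that("reporter-pair enumeration matches a brute-force oracle", {
  # oracle: exhaustive scan over all donors x positions x canonical edits,
  # written independently of enumerate_reporter_pairs()
  bases <- c("A", "C", "G", "T")
  donors <- as.vector(outer(bases, bases, paste0))
  oracle <- list(ABE = list(), CBE = list())
  for (don in donors) {
    if (classify_splice_donor(don) != "inactive") next
    for (pos in 1:2) {
      b <- substr(don, pos, pos)
      for (ed in c("ABE", "CBE")) {
        sub <- c(ABE = "A", CBE = "C")[[ed]]
        prod <- c(ABE = "G", CBE = "T")[[ed]]
        if (b != sub) next
        edited <- don
        substr(edited, pos, pos) <- prod
        if (classify_splice_donor(edited) == "active") {
          oracle[[ed]][[length(oracle[[ed]]) + 1L]] <-
            c(don, pos, edited)
        }
      }
    }
  }
  oracle_abe <- do.call(rbind, oracle$ABE)
  oracle_cbe <- do.call(rbind, oracle$CBE)

  abe <- enumerate_reporter_pairs("ABE")
  cbe <- enumerate_reporter_pairs("CBE")
  expect_setequal(paste(abe$inactive_donor, abe$edited_donor_position,
                        abe$active_donor),
                  paste(oracle_abe[, 1], oracle_abe[, 2], oracle_abe[, 3]))
  expect_setequal(paste(cbe$inactive_donor, cbe$edited_donor_position,
                        cbe$active_donor),
                  paste(oracle_cbe[, 1], oracle_cbe[, 2], oracle_cbe[, 3]))
  # TC -> TT is one of the CBE-rescuable donors
  expect_true(any(cbe$inactive_donor == "TC" & cbe$active_donor == "TT"))

  # 'AC' is the unique donor rescuable by both editors independently
  both <- enumerate_reporter_pairs("both")
  expect_equal(unique(both$inactive_donor), "AC")
  expect_setequal(both$active_donor, c("GC", "AT"))
  expect_equal(both$edited_donor_position[both$editor == "ABE"], 1L)
  expect_equal(both$edited_donor_position[both$editor == "CBE"], 2L)

  # every pair satisfies the conversion identity
  for (i in seq_len(nrow(both))) {
    edited <- apply_base_edit(both$inactive_donor[i], both$editor[i],
                              both$edited_donor_position[i] - 1L)
    expect_equal(as.character(edited), both$active_donor[i])
  }

  # no active context exists when both flanks are altered
  expect_equal(nrow(enumerate_reporter_pairs("ABE", flank5 = "C",
                                             flank3 = "CCCC")), 0L)
})

test_that("PAM placement enumeration matches a brute-force scan", {
  # single 'GG' placed so the edited base falls at protospacer position 6:
  # PAM at [p, p+3) with protospacer [p-20, p); edited coord = p - 20 + 5
  ref <- strrep("A", 60)
  edited <- 25L
  p <- edited - 5L + 20L  # PAM start such that edited sits at position 6
  ref <- with_sub(with_sub(ref, p + 1L, "G"), p + 2L, "G")
  hits <- enumerate_pam_placements(ref, edited)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$proto_start, p - 20L)
  expect_equal(hits$proto_position, 6L)

  # brute-force oracle over every NGG placement on either strand
  brute <- function(reference, ed_pos, window = c(4L, 8L), L = 20L) {
    v <- strsplit(reference, "")[[1]]
    len <- length(v)
    out <- NULL
    for (p0 in 0:(len - 3)) {
      if (p0 - L >= 0 && v[p0 + 2] == "G" && v[p0 + 3] == "G") {
        pos <- ed_pos - (p0 - L) + 1L
        if (pos >= window[1] && pos <= window[2]) {
          out <- rbind(out, c(p0 - L, 1L))
        }
      }
      if (p0 + 3 + L <= len && v[p0 + 1] == "C" && v[p0 + 2] == "C") {
        pos <- (p0 + 3L + L) - ed_pos
        if (pos >= window[1] && pos <= window[2]) {
          out <- rbind(out, c(p0 + 3L, 2L))
        }
      }
    }
    out
  }
  set.seed(42)
  for (rep in 1:10) {
    ref2 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    ed2 <- sample(0:59, 1)
    got <- enumerate_pam_placements(ref2, ed2)
    want <- brute(ref2, ed2)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_setequal(paste(got$proto_start, got$strand),
                      paste(want[, 1], c("+", "-")[want[, 2]]))
    }
  }

  # no GG or CC anywhere: empty
  none <- enumerate_pam_placements(paste(rep(c("A", "T"), 20), collapse = ""),
                                   10L)
  expect_equal(nrow(none), 0L)
  expect_error(enumerate_pam_placements("ACGT", 1L), "shorter")
})

test_that("editing-window bounds are inclusive at 4 and 8", {
  # one + strand PAM; slide the edited base across protospacer positions
  ref <- strrep("T", 60)
  p <- 40L  # PAM [40, 43): set GG at coords 41, 42
  ref <- with_sub(with_sub(ref, 41L, "G"), 42L, "G")
  proto_start <- p - 20L
  pos_of <- function(coord) coord - proto_start + 1L
  for (pp in c(4L, 8L)) {
    hits <- enumerate_pam_placements(ref, proto_start + pp - 1L)
    expect_true(any(hits$strand == "+" & hits$proto_start == proto_start),
                info = sprintf("position %d should be inside", pp))
  }
  for (pp in c(3L, 9L)) {
    hits <- enumerate_pam_placements(ref, proto_start + pp - 1L)
    expect_false(any(hits$strand == "+" & hits$proto_start == proto_start),
                 info = sprintf("position %d should be outside", pp))
  }
})

test_that("target_site validates geometry and editable positions", {
  site <- abe_site()
  expect_equal(site$cut_site, 42L)
  expect_equal(site$pam_start, 46L)
  expect_equal(site$proto_end, 46L)
  expect_error(target_site(test_reference, proto_start = 10),
               "no NGG PAM")
  expect_error(target_site(test_reference, proto_start = 26,
                           editable_positions = data.frame(
                             position = 30, from = "C", to = "T")),
               "does not carry")
  expect_error(target_site(test_reference, proto_start = 70), "outside")
})
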