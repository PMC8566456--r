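test_that("prefix identity counts matched reference prefix positions", {
  ref <- test_reference
  expect_equal(prefix_identity(align_semi_global(ref, ref)), 1.0)
  # substitutions at exactly 5 of the first 20 positions
  expect_equal(prefix_identity(align_semi_global(make_sub_read(5), ref)),
               0.75)
  # a read starting at reference position 10 leaves 10 prefix positions
  # uncovered
  late <- substr(ref, 11, nchar(ref))
  expect_lte(prefix_identity(align_semi_global(late, ref)), 0.5)
  # deletions inside the prefix count as non-matches
  expect_equal(prefix_identity(align_semi_global(with_del(ref, 10, 2), ref)),
               18 / 20)
  expect_error(prefix_identity(align_semi_global(ref, ref), 0), "prefix_len")
  expect_error(prefix_identity(align_semi_global(ref, ref), 1000),
               "prefix_len")
})

test_that("read retention flips on exactly at the 75% identity threshold", {
  idents <- seq(0.50, 1.00, by = 0.05)
  reads <- vapply(round((1 - idents) * 20), make_sub_read, character(1))
  res <- filter_reads(reads, test_reference)
  retained <- reads %in% res$retained$seq
  expect_equal(retained, idents >= 0.75)
  expect_equal(nrow(res$retained) + nrow(res$filtered_out), length(reads))
  # threshold 0 retains everything; raising the threshold is monotone
  expect_equal(nrow(filter_reads(reads, test_reference,
                                 threshold = 0)$retained), length(reads))
  counts <- vapply(c(0, 0.5, 0.75, 0.9, 1),
                   function(th) nrow(filter_reads(reads, test_reference,
                                                  threshold = th)$retained),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # empty input
  empty <- filter_reads(character(0), test_reference)
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(nrow(empty$filtered_out), 0L)
})

test_that("read calling distinguishes the outcome classes", {
  site <- abe_site()
  ref <- test_reference
  call1 <- function(rd, site, ...) {
    call_read(align_semi_global(rd, site$reference), site, ...)
  }
  expect_equal(call1(ref, site)$status, "unedited")
  # intended A-to-G at the target adenine
  ed <- call1(with_sub(ref, 30, "G"), site)
  expect_equal(ed$status, "edited")
  expect_true(ed$covers_target)
  expect_equal(ed$conversions[[1]]$position, 30L)
  # unexpected conversion at the target: byproduct (C-to-G style)
  cbe <- cbe_site()
  expect_equal(call1(with_sub(ref, 31, "G"), cbe)$status, "byproduct")
  expect_equal(call1(with_sub(ref, 31, "T"), cbe)$status, "edited")
  # partial editing requires >= 2 editable positions
  two <- target_site(test_reference, proto_start = 26,
                     editable_positions = data.frame(
                       position = c(30, 32), from = c("A", "A"),
                       to = c("G", "G")))
  expect_equal(call1(with_sub(ref, 30, "G"), two)$status, "partially_edited")
  expect_equal(call1(with_sub(with_sub(ref, 30, "G"), 32, "G"), two)$status,
               "edited")
})

test_that("indel calling is confined to the +/-2 bp cut-site window", {
  site <- abe_site()  # cut site at coordinate 42
  ref <- test_reference
  call1 <- function(rd, ...) {
    call_read(align_semi_global(rd, ref), site, ...)
  }
  # 1-bp deletion exactly 2 bp from the cut site (canonical coords 40, 44)
  expect_equal(call1(with_del(ref, 40, 1))$status, "indel")
  expect_equal(call1(with_del(ref, 44, 1))$status, "indel")
  # 3 bp away (canonical placement outside [40, 44]): not an indel
  expect_equal(call1(with_del(ref, 39, 1))$status, "unedited")
  expect_equal(call1(with_del(ref, 45, 1))$status, "unedited")
  # insertions anchored in the window count, any size
  expect_equal(call1(with_ins(ref, 42, "ACG"))$status, "indel")
  expect_equal(call1(with_ins(ref, 42, strrep("ACG", 4)))$status, "indel")
  # a large deletion overlapping the window from outside counts
  expect_equal(call1(with_del(ref, 38, 6))$status, "indel")
  # widening the window never un-calls an indel
  expect_equal(call1(with_del(ref, 39, 1), window_halfwidth = 4)$status,
               "indel")
  # strict flanks: a stray substitution disqualifies the indel call
  messy <- with_sub(with_del(ref, 40, 1), 20, "C")
  expect_equal(call1(messy)$status, "unedited")
  expect_equal(call1(messy, strict_flanks = FALSE)$status, "indel")
  # ... but a conversion at the designated editable position does not
  edited_indel <- with_sub(with_del(ref, 40, 1), 30, "G")
  expect_equal(call1(edited_indel)$status, "indel")
})

test_that("quantify reproduces constructed counts exactly", {
  site <- abe_site()
  ref <- test_reference
  reads <- c(rep(ref, 850), rep(with_del(ref, 42, 1), 100),
             rep(with_sub(ref, 30, "G"), 50))
  q <- quantify(reads, site)
  expect_equal(q$n_total, 1000L)
  expect_equal(q$n_retained, 1000L)
  expect_equal(q$n_indel, 100L)
  expect_equal(q$indel_frequency, 0.100)
  expect_equal(q$intended_edit_frequency, 50 / 1000)
  g <- glance(q)
  expect_equal(g$n_retained, 1000L)
  expect_equal(g$indel_frequency, 0.1)
  # conservation across statuses
  expect_equal(sum(table(q$calls$status)), q$n_retained)
})

test_that("undefined frequencies are NA, never zero", {
  site <- abe_site()
  junk <- rep(strrep("T", 40), 5)  # nothing passes the prefix filter
  q <- quantify(junk, site)
  expect_equal(q$n_retained, 0L)
  expect_true(is.na(q$indel_frequency))
  expect_true(is.na(q$intended_edit_frequency))
  q0 <- quantify(character(0), site)
  expect_equal(q0$n_total, 0L)
  expect_true(is.na(q0$indel_frequency))
})

test_that("conversion matrix counts bases per reference column", {
  site <- abe_site()
  ref <- test_reference
  reads <- c(rep(ref, 6), rep(with_sub(ref, 30, "G"), 3),
             with_del(ref, 40, 2))
  cm <- conversion_matrix(reads, site, flank = 5)
  expect_setequal(unique(cm$base), c("A", "C", "G", "T", "del", "other"))
  # columns span protospacer +/- flank
  expect_equal(range(cm$position), c(26 - 5, 46 + 5 - 1))
  # every column sums to the number of covering reads
  sums <- tapply(cm$count, cm$position, sum)
  ncov <- tapply(cm$n_covering, cm$position, unique)
  expect_equal(as.integer(sums), as.integer(ncov))
  # the edited column splits 7 A / 3 G
  at30 <- cm[cm$position == 30, ]
  expect_equal(at30$count[at30$base == "A"], 7L)
  expect_equal(at30$count[at30$base == "G"], 3L)
  # the deletion increments 'del' at its canonical columns 40 and 41
  expect_equal(cm$count[cm$position == 40 & cm$base == "del"], 1L)
  expect_equal(cm$count[cm$position == 41 & cm$base == "del"], 1L)
  # a clean sample is 100% reference base everywhere
  clean <- conversion_matrix(rep(ref, 4), site, flank = 5)
  refmatch <- clean[clean$base == clean$ref_base, ]
  expect_true(all(refmatch$fraction == 1))
})

test_that("tidy and glance expose the result tables", {
  site <- cbe_site()
  reads <- c(rep(test_reference, 3), with_sub(test_reference, 31, "T"))
  q <- quantify(reads, site)
  expect_s3_class(tidy(q), "tbl_df")
  expect_equal(nrow(glance(q)), 1L)
  expect_equal(glance(q)$intended_edit_frequency, 0.25)
  expect_equal(q$per_editable$frac_expected, 0.25)
  p <- ggplot2::autoplot(q)
  expect_s3_class(p, "ggplot")
})
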