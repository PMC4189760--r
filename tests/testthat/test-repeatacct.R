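# Repeat annotation parsing, masking, density accounting, naive masker.

rm_out_fixture <- function(rows) {
  hdr <- c("   SW  perc perc perc  query     position in query ...",
           "score  div. del. ins.  sequence  begin end ...",
           "")
  p <- tempfile(fileext = ".out")
  writeLines(c(hdr, rows), p)
  p
}

test_that("rm_out coordinates convert from 1-based inclusive", {
  p <- rm_out_fixture(
    " 1500 10.1 0.2 0.3 readF 11 20 (500) + Gypsy-12_PT LTR/Gypsy 1 300 (0) 1")
  feats <- read_repeat_annotations(p)
  expect_identical(feats$start, 10L)
  expect_identical(feats$end, 20L)
  expect_identical(feats$class_path, "ClassI/LTR/Gypsy")
  expect_identical(feats$family, "Gypsy-12_PT")
})

test_that("class mapping falls back to Unclassified with a warning", {
  p <- rm_out_fixture(
    " 900 5.0 0.1 0.1 readF 1 50 (100) + WeirdThing MysteryClass 1 50 (0) 1")
  expect_warning(feats <- read_repeat_annotations(p), "Unclassified")
  expect_identical(feats$class_path, "Unclassified")
})

test_that("score cutoff drops and counts features; empty file is empty", {
  p <- rm_out_fixture(c(
    " 100 5.0 0.1 0.1 rF 1 50 (100) + Copia-x LTR/Copia 1 50 (0) 1",
    " 900 5.0 0.1 0.1 rF 60 120 (40) + Copia-x LTR/Copia 1 61 (0) 2"))
  feats <- read_repeat_annotations(p, min_score = 500)
  expect_identical(nrow(feats), 1L)
  expect_identical(attr(feats, "n_dropped"), 1L)
  p0 <- rm_out_fixture(character(0))
  expect_identical(nrow(read_repeat_annotations(p0)), 0L)
})

test_that("generic TSV dialect round-trips through the writer", {
  feats <- data.frame(read_id = "aF", start = 5L, end = 25L,
                      family = "synCopia1",
                      class_path = "ClassI/LTR/Copia", score = 20)
  p <- tempfile(fileext = ".tsv")
  write_repeat_features(feats, p)
  back <- read_repeat_annotations(p, dialect = "tsv")
  expect_identical(back$start, 5L)
  expect_identical(back$end, 25L)
  expect_identical(back$class_path, "ClassI/LTR/Copia")
})

test_that("masking hard-masks the union of intervals", {
  set <- bes_set(c(aF = "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT" ,
                   bF = strrep("ACGT", 30)), min_len = 1)
  f <- function(id, s, e) data.frame(read_id = id, start = s, end = e,
                                     family = "x", class_path = "Unclassified",
                                     score = NA_real_)
  m1 <- mask_repeats(set, f("aF", 0, 4))
  expect_identical(substr(m1$seq[["aF"]], 1, 8), "NNNNACGT")
  # overlapping features mask their union
  m2 <- mask_repeats(set, rbind(f("aF", 0, 4), f("aF", 2, 6)))
  expect_identical(substr(m2$seq[["aF"]], 1, 8), "NNNNNNGT")
  # no features -> identity
  expect_identical(mask_repeats(set, f("aF", 0, 4)[0, ])$seq, set$seq)
  # out-of-bounds features are clipped with a warning
  expect_warning(m3 <- mask_repeats(set, f("aF", 40, 99)), "bounds")
  expect_identical(nchar(m3$seq[["aF"]]), nchar(set$seq[["aF"]]))
  # soft masking lowercases instead
  m4 <- mask_repeats(set, f("aF", 0, 4), soft = TRUE)
  expect_identical(substr(m4$seq[["aF"]], 1, 5), "acgtA")
})

test_that("density uses interval unions, invariant to order/duplication", {
  f <- data.frame(read_id = "rF", start = c(10L, 15L), end = c(20L, 30L),
                  family = "x", class_path = "ClassI/LTR/Copia",
                  score = NA_real_)
  rep1 <- repeat_report(f, 1000)
  expect_identical(rep1$total_masked_nt, 20L)
  expect_equal(rep1$density_percent, 2)
  # duplication and re-ordering change nothing
  rep2 <- repeat_report(rbind(f[2:1, ], f), 1000)
  expect_identical(rep2$total_masked_nt, rep1$total_masked_nt)
  # same interval on different reads counts twice
  f2 <- f; f2$read_id <- "sF"
  expect_identical(repeat_report(rbind(f, f2), 1000)$total_masked_nt, 40L)
})

test_that("per-class unions equal the overall union when classes do not overlap", {
  f <- data.frame(read_id = "rF", start = c(0L, 100L), end = c(50L, 180L),
                  family = c("c", "g"),
                  class_path = c("ClassI/LTR/Copia", "ClassI/LTR/Gypsy"),
                  score = NA_real_)
  rep <- repeat_report(f, 1000)
  expect_identical(sum(rep$per_class$masked_nt), rep$total_masked_nt)
  expect_identical(rep$n_elements, 2L)
})

test_that("naive masker finds exact planted copies and nothing else", {
  set.seed(21)
  lib <- stats::setNames(rand_dna(300), "fam1 ClassI/LTR/Copia")
  read <- paste0(rand_dna(150), lib[[1]], rand_dna(150))
  set <- bes_set(stats::setNames(c(read, rand_dna(400)),
                                 c("hitF", "missF")))
  feats <- naive_repeat_search(set, lib, k = 12, min_len = 50,
                               max_mismatch_frac = 0)
  expect_identical(nrow(feats), 1L)
  expect_identical(feats$read_id, "hitF")
  expect_identical(feats$start, 150L)
  expect_identical(feats$end, 450L)
  expect_identical(feats$class_path, "ClassI/LTR/Copia")
  # reverse-complement copies are found on the minus strand
  rcread <- paste0(rand_dna(100), revcomp(lib[[1]]), rand_dna(100))
  rcfeats <- naive_repeat_search(bes_set(c(rcF = rcread)), lib, k = 12,
                                 min_len = 50, max_mismatch_frac = 0)
  expect_identical(rcfeats$start, 100L)
  expect_identical(rcfeats$end, 400L)
  expect_error(naive_repeat_search(set, character(0)), "empty")
})

test_that("mutated copies are still covered at 2% divergence", {
  # simulation property: tolerance 5%, mutation 2% -> >= 90% coverage
  set.seed(31)
  lib <- stats::setNames(rand_dna(400), "fam1 ClassI/LTR/Gypsy")
  for (i in 1:10) {
    copy <- strsplit(lib[[1]], "")[[1]]
    hit <- which(runif(400) < 0.02)
    for (h in hit) copy[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                             copy[h]), 1)
    read <- paste0(rand_dna(100), paste(copy, collapse = ""),
                   rand_dna(100))
    feats <- naive_repeat_search(bes_set(c(mF = read)), lib, k = 12,
                                 min_len = 50, max_mismatch_frac = 0.05)
    covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
      pmax(feats$start, 100) + 1, pmin(feats$end, 500)))))
    expect_gte(covered, 0.9 * 400)
  }
})
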