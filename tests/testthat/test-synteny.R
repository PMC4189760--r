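# SAM parsing and microsynteny pair classification.

test_that("SAM records convert to 0-based half-open intervals", {
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr1\tLN:100000",
               sam_line("c1F", 0, "chr1", 1, 60, "100M"),
               sam_line("c1R", 16, "chr1", 5001, 60, "50M10D40M"),
               sam_line("c2F", 4, "*", 0, 0, "*"),
               sam_line("c2R", 0, "chr1", 900, 3, "80M"),
               sam_line("c3F", 256, "chr1", 10, 60, "80M"),
               sam_line("c3R", 2048, "chr1", 10, 60, "80M")), p)
  aln <- read_end_alignments(p, min_mapq = 20)
  expect_identical(nrow(aln), 4L)   # secondary + supplementary dropped
  f <- aln[aln$read_id == "c1F", ]
  expect_identical(f$start, 0L)
  expect_identical(f$stop, 100L)    # POS=1, span 100 -> [0, 100)
  expect_identical(f$strand, "+")
  r <- aln[aln$read_id == "c1R", ]
  expect_identical(r$stop, 5100L)   # 50M 10D 40M consumes 100 reference nt
  expect_identical(r$strand, "-")
  expect_false(aln$mapped[aln$read_id == "c2F"])
  expect_false(aln$mapped[aln$read_id == "c2R"])  # MAPQ 3 < 20
  expect_identical(aln$clone_id[aln$read_id == "c1F"], "c1")
})

test_that("classifier matches the exhaustive hand truth table", {
  # all (same/different reference) x (span below/within/above the
  # 15-350 kb window) x (4 strand combinations) x (F left / R left)
  span_of <- list(below = 10000, within = 100000, above = 6000000)
  for (same_ref in c(TRUE, FALSE)) {
    for (span_name in names(span_of)) {
      for (fs in c("+", "-")) for (rs in c("+", "-")) {
        for (f_left in c(TRUE, FALSE)) {
          span <- span_of[[span_name]]
          left <- end_aln(rname = "chr1", start = 0, stop = 600,
                          strand = if (f_left) fs else rs)
          right <- end_aln(rname = if (same_ref) "chr1" else "chr2",
                           start = span - 600, stop = span,
                           strand = if (f_left) rs else fs)
          f <- if (f_left) left else right
          r <- if (f_left) right else left
          got <- classify_pair(f, r)$category
          want <- if (!same_ref) {
            "PE_non_colocalized"
          } else if (span_name != "within") {
            "PE_gapped"
          } else if (fs != rs && left$strand == "+") {
            "PE_collinear"
          } else {
            "PE_rearranged"
          }
          expect_identical(got, want,
                           info = sprintf("same=%s span=%s F=%s R=%s f_left=%s",
                                          same_ref, span_name, fs, rs, f_left))
        }
      }
    }
  }
})

test_that("unmapped and single-end rules apply before pair rules", {
  un <- end_aln(mapped = FALSE, rname = NA, start = NA, stop = NA,
                strand = NA)
  ok <- end_aln()
  expect_identical(classify_pair(un, un)$category, "unmapped")
  expect_identical(classify_pair(ok, un)$category, "SE")
  expect_identical(classify_pair(un, ok)$category, "SE")
  expect_identical(classify_pair(NULL, ok)$category, "SE")
  expect_identical(classify_pair(NULL, NULL)$category, "unmapped")
  expect_error(classify_pair(end_aln(start = 5, stop = 5),
                             end_aln(start = 100000, stop = 100600)),
               "zero-length")
})

test_that("window bounds are inclusive and span uses outer coordinates", {
  f <- end_aln(start = 0, stop = 600, strand = "+")
  mk_r <- function(span) end_aln(start = span - 600, stop = span,
                                 strand = "-")
  expect_identical(classify_pair(f, mk_r(15000))$category, "PE_collinear")
  expect_identical(classify_pair(f, mk_r(350000))$category, "PE_collinear")
  expect_identical(classify_pair(f, mk_r(14999))$category, "PE_gapped")
  expect_identical(classify_pair(f, mk_r(350001))$category, "PE_gapped")
  expect_identical(classify_pair(f, mk_r(100000))$span_bp, 100000)
  # strand-opposition-only mode accepts outward-facing opposite strands
  fo <- end_aln(start = 0, stop = 600, strand = "-")
  ro <- end_aln(start = 99400, stop = 100000, strand = "+")
  expect_identical(classify_pair(fo, ro)$category, "PE_rearranged")
  expect_identical(classify_pair(fo, ro, orientation = "opposite")$category,
                   "PE_collinear")
})

test_that("classification is symmetric in its two arguments", {
  set.seed(8)
  flip <- function(a) { a$strand <- if (a$strand == "+") "-" else "+"; a }
  for (i in 1:50) {
    f <- end_aln(rname = sample(c("c1", "c2"), 1),
                 start = s1 <- sample(1e6, 1), stop = s1 + 600,
                 strand = sample(c("+", "-"), 1))
    r <- end_aln(rname = sample(c("c1", "c2"), 1),
                 start = s2 <- sample(1e6, 1), stop = s2 + 600,
                 strand = sample(c("+", "-"), 1))
    # the FR rule depends only on geometry, so a plain label swap (the
    # same two alignments handed over in the other order) cannot change
    # the category
    expect_identical(classify_pair(f, r)$category,
                     classify_pair(r, f)$category)
    # relabelling ends *and* flipping both strands preserves the category
    # under the strand-opposition-only rule
    expect_identical(
      classify_pair(f, r, orientation = "opposite")$category,
      classify_pair(flip(r), flip(f), orientation = "opposite")$category)
  }
})

test_that("span_kb reproduces published interval arithmetic", {
  expect_identical(span_kb(15558, 130159), 114.6)
  expect_identical(span_kb(2324226, 2502417), 178.2)
  expect_identical(span_kb(5, 5), 0)
})

test_that("category summaries count SE and PE correctly", {
  cls <- data.frame(category = c("SE", "SE", "SE", "PE_collinear",
                                 "PE_collinear", "PE_gapped", "unmapped"))
  s <- synteny_summary(cls)
  expect_identical(s$n_se, 3L)
  expect_identical(s$n_pe, 3L)
  expect_identical(s$n_matches, 6L)
  s0 <- synteny_summary(cls[0, , drop = FALSE])
  expect_true(all(s0$category_counts == 0L))
})
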