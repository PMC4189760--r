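# Synthetic genome / library generator: determinism, planted truth,
# capacity, contamination, reference rearrangements.

tiny_spec <- function(...) {
  args <- list(genome_length = 3e5, n_clones = 50, organellar_rate = 0,
               duplicate_rate = 0, seed = 5)
  args[names(list(...))] <- list(...)
  do.call(survey_spec, args)
}

test_that("spec invariants are validated", {
  expect_error(survey_spec(ssr_class_mix = rep(0.2, 6)), "sum to 1")
  expect_error(survey_spec(insert_mean = 40, insert_min = 50,
                           insert_max = 196))
  expect_error(survey_spec(genome_length = -1))
})

test_that("nothing planted means empty truth and no detections", {
  spec <- survey_spec(genome_length = 10000, gc_fraction = 0.5,
                      ssr_density = 0,
                      repeat_families = data.frame(
                        family = character(0), class_path = character(0),
                        consensus_len = integer(0), copies = integer(0)),
                      n_clones = 0, seed = 3)
  gen <- generate_genome(spec)
  expect_identical(nchar(gen$genome), 10000L)
  expect_identical(nrow(gen$truth$ssr), 0L)
  expect_identical(nrow(gen$truth$repeats), 0L)
  expect_identical(nrow(find_ssrs(gen$genome)), 0L)
})

test_that("identical (spec, seed) gives byte-identical output", {
  spec <- tiny_spec()
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  l1 <- simulate_library(g1)
  l2 <- simulate_library(g2)
  expect_identical(l1$set$seq, l2$set$seq)
  expect_identical(l1$reads, l2$reads)
  # a different seed changes the genome
  g3 <- generate_genome(tiny_spec(seed = 6))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("planted SSR truth is recovered exactly from the genome", {
  spec <- survey_spec(genome_length = 1e5, ssr_density = 15, n_clones = 0,
                      seed = 9)
  gen <- generate_genome(spec)
  det <- find_ssrs(c(g = gen$genome))
  expect_identical(det$start, gen$truth$ssr$start)
  expect_identical(det$end, gen$truth$ssr$end)
  expect_identical(det$canonical, gen$truth$ssr$canonical)
  expect_identical(nrow(det), 15L)
})

test_that("a single planted mono locus round-trips through the miner", {
  spec <- survey_spec(genome_length = 1e4, ssr_density = 10,
                      ssr_class_mix = c(1, 0, 0, 0, 0, 0),
                      repeat_families = data.frame(
                        family = character(0), class_path = character(0),
                        consensus_len = integer(0), copies = integer(0)),
                      n_clones = 0, seed = 2)
  gen <- generate_genome(spec)
  expect_identical(nrow(gen$truth$ssr), 1L)
  expect_identical(gen$truth$ssr$class, "mono")
  det <- find_ssrs(gen$genome)
  expect_identical(det$start, gen$truth$ssr$start)
  expect_identical(det$total_len,
                   gen$truth$ssr$end - gen$truth$ssr$start)
})

test_that("over-planting raises a capacity error", {
  expect_error(generate_genome(survey_spec(
    genome_length = 20000,
    repeat_families = data.frame(family = "f", class_path = "Unclassified",
                                 consensus_len = 5000L, copies = 10L),
    n_clones = 0, seed = 1)), "capacity")
})

test_that("library counting follows the pairing parameters", {
  spec <- tiny_spec(unpaired_fraction = 0, n_clones = 100)
  lib <- simulate_library(generate_genome(spec))
  expect_identical(nrow(lib$reads), 200L)
  expect_identical(sum(lib$reads$end == "F"), 100L)
  expect_identical(sum(lib$reads$end == "R"), 100L)
  # degenerate insert distribution
  spec2 <- tiny_spec(insert_sd = 0, n_clones = 30)
  lib2 <- simulate_library(generate_genome(spec2))
  expect_true(all(lib2$clones$insert_len == 108000L))
  # end reads are substrings of the genome at the recorded coordinates
  gen <- generate_genome(spec2)
  for (i in 1:5) {
    rd <- lib2$reads[i, ]
    seg <- substr(gen$genome, rd$gstart + 1, rd$gend)
    if (rd$orient == "-") seg <- revcomp(seg)
    expect_identical(unname(lib2$set$seq[[rd$read_id]]), seg)
  }
})

test_that("organellar contamination hits the planted rate", {
  # scaled-down version of the published-scale binomial check: with n
  # reads and per-read rate p, the organellar count must fall inside the
  # central 99% binomial interval
  spec <- tiny_spec(organellar_rate = 0.05, n_clones = 300, seed = 17)
  lib <- simulate_library(generate_genome(spec))
  n <- nrow(lib$reads)
  n_org <- sum(lib$reads$provenance %in% c("chloroplast", "mitochondrial"))
  expect_gte(n_org, qbinom(0.005, n, 0.05))
  expect_lte(n_org, qbinom(0.995, n, 0.05))
  # organellar reads carry no nuclear coordinates
  expect_true(all(is.na(lib$reads$gstart[lib$reads$provenance ==
                                           "chloroplast"])))
  expect_error(simulate_library(generate_genome(spec)$genome, spec,
                                organellar = NULL),
               "organellar")
})

test_that("planted duplicates produce the requested redundancy", {
  spec <- tiny_spec(duplicate_rate = 0.1, n_clones = 150, seed = 23)
  lib <- simulate_library(generate_genome(spec))
  d <- sum(lib$reads$provenance == "duplicate")
  expect_equal(d / nrow(lib$reads), 0.1, tolerance = 0.01)
  expect_equal(redundancy(lib$set), d / nrow(lib$reads),
               tolerance = 0.005)
})

test_that("identity reference classifies fully mapped pairs collinear", {
  lib <- simulate_library(generate_genome(tiny_spec(unpaired_fraction = 0)))
  ref <- derive_reference(lib)
  expect_true(all(ref$pair_truth$category == "PE_collinear"))
  expect_identical(ref$reference[["ref1"]], lib$genome$genome)
})

test_that("edits produce the expected categories", {
  spec <- tiny_spec(unpaired_fraction = 0, n_clones = 40, seed = 19)
  lib <- simulate_library(generate_genome(spec))
  cl <- lib$clones
  # pick a clone and invert a window covering exactly its F end
  target <- cl[cl$insert_len > 60000, ][1, ]
  f_len <- lib$reads$length[lib$reads$read_id == paste0(target$clone_id,
                                                        "F")]
  inv <- list(type = "inversion", pos = max(0, target$start - 1000),
              len = f_len + 2000)
  ref <- derive_reference(lib, list(inv))
  expect_identical(
    ref$pair_truth$category[ref$pair_truth$clone_id == target$clone_id],
    "PE_rearranged")
  # an insertion larger than d_max between the ends -> gapped
  mid <- target$start + round(target$insert_len / 2)
  ref2 <- derive_reference(lib, list(list(type = "insertion", pos = mid,
                                          len = 400000)))
  expect_identical(
    ref2$pair_truth$category[ref2$pair_truth$clone_id == target$clone_id],
    "PE_gapped")
  # a translocation of one end -> non co-localized
  ref3 <- derive_reference(lib, list(list(
    type = "translocation", pos = max(0, target$start - 1000),
    len = f_len + 2000)))
  expect_identical(
    ref3$pair_truth$category[ref3$pair_truth$clone_id == target$clone_id],
    "PE_non_colocalized")
  # a deletion swallowing the F end -> SE
  ref4 <- derive_reference(lib, list(list(
    type = "deletion", pos = max(0, target$start - 1000),
    len = f_len + 2000)))
  expect_identical(
    ref4$pair_truth$category[ref4$pair_truth$clone_id == target$clone_id],
    "SE")
  expect_error(derive_reference(lib, list(
    list(type = "inversion", pos = 1000, len = 5000),
    list(type = "deletion", pos = 3000, len = 5000))), "overlap")
})

test_that("truth SAM round-trips through the classifier exactly", {
  spec <- tiny_spec(n_clones = 60, organellar_rate = 0.02,
                    duplicate_rate = 0.05, seed = 29)
  lib <- simulate_library(generate_genome(spec))
  ref <- derive_reference(lib, list(
    list(type = "inversion", pos = 50000, len = 30000),
    list(type = "translocation", pos = 150000, len = 40000),
    list(type = "deletion", pos = 250000, len = 20000)))
  p <- tempfile(fileext = ".sam")
  write_truth_sam(ref, p)
  cls <- classify_pairs(read_end_alignments(p))
  m <- merge(cls, ref$pair_truth, by = "clone_id")
  expect_identical(nrow(m), nrow(ref$pair_truth))
  expect_identical(m$category.x, m$category.y)
})

test_that("defaults recover GC, SSR density and repeat fraction over seeds", {
  # distributional recovery at reduced scale (10 seeds, 200 kb genomes)
  gcs <- dens <- reps <- numeric(10)
  for (s in 1:10) {
    spec <- survey_spec(genome_length = 2e5, n_clones = 50,
                        organellar_rate = 0, duplicate_rate = 0, seed = s)
    gen <- generate_genome(spec)
    lib <- simulate_library(gen)
    gcs[s] <- gc_content(lib$set)$gc_percent
    dens[s] <- ssr_summary(find_ssrs(lib$set),
                           lib$set$total_nt)$density_per_100kb
    feats <- naive_repeat_search(lib$set, gen$consensi, k = 16,
                                 min_len = 50, max_mismatch_frac = 0)
    reps[s] <- repeat_report(feats, lib$set$total_nt)$density_percent
  }
  expect_lte(abs(mean(gcs) - 41.9), 3 * sd(gcs) / sqrt(10))
  expect_lte(abs(mean(dens) - 10.8), 3 * sd(dens) / sqrt(10))
  planted_pct <- 100 * (0.083 + 0.106 + 0.0045 + 0.0025)
  expect_lte(abs(mean(reps) - planted_pct), 3 * sd(reps) / sqrt(10))
})

test_that("spec JSON round-trips", {
  spec <- tiny_spec(rearrangements = list(list(type = "inversion",
                                               pos = 100, len = 50)))
  p <- tempfile(fileext = ".json")
  write_survey_spec(spec, p)
  back <- read_survey_spec(p)
  expect_equal(back$genome_length, spec$genome_length)
  expect_equal(back$ssr_class_mix, spec$ssr_class_mix)
  expect_equal(back$repeat_families, spec$repeat_families)
  expect_equal(length(back$rearrangements), 1L)
})
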