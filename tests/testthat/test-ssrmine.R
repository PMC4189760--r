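# Perfect-SSR mining: canonicalization, thresholds, maximality, overlap
# resolution, and equivalence with the brute-force enumerator.

test_that("canonical_motif groups rotations and reverse complements", {
  expect_identical(canonical_motif(c("GA", "TC", "CT", "AG")),
                   rep("AG", 4))
  # the GAA group: all six members collapse to the lexicographic minimum
  grp <- c("GAA", "AAG", "AGA", "CTT", "TTC", "TCT")
  expect_identical(unique(canonical_motif(grp)), "AAG")
  expect_identical(canonical_motif("A"), "A")
})

test_that("canonical_motif is idempotent and constant on random orbits", {
  set.seed(11)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    u <- rand_dna(k)
    while (!bessurvey:::is_primitive(u)) u <- rand_dna(k)
    can <- canonical_motif(u)
    expect_identical(canonical_motif(can), can)   # idempotent
    rots <- vapply(seq_len(k), function(i)
      paste0(substr(u, i, k), substr(u, 1, i - 1)), "")
    orbit <- c(rots, revcomp(rots))
    expect_identical(unique(canonical_motif(orbit)), can)
    expect_length(unique(orbit[can == orbit]), if (can %in% orbit) 1 else 0)
  }
})

test_that("canonical_motif rejects non-primitive and invalid units", {
  expect_error(canonical_motif("ATAT"), "primitive")
  expect_error(canonical_motif("AN"), "A/C/G/T")
  expect_error(canonical_motif("AATTGGC"), "1-6")
})

test_that("class thresholds sit exactly at the documented boundaries", {
  # mono: >= 10 nt
  expect_identical(nrow(find_ssrs(strrep("A", 10))), 1L)
  expect_identical(nrow(find_ssrs(strrep("A", 9))), 0L)
  # di: >= 5 units
  di <- find_ssrs("AGAGAGAGAG")
  expect_identical(di$canonical, "AG")
  expect_identical(di$n_units, 5L)
  expect_identical(nrow(find_ssrs("AGAGAGAG")), 0L)
  # tri..hexa: >= 3 units
  expect_identical(nrow(find_ssrs(strrep("ACG", 3))), 1L)
  expect_identical(nrow(find_ssrs(strrep("ACG", 2))), 0L)
  expect_identical(nrow(find_ssrs(strrep("ACGTAG", 3))), 1L)
})

test_that("hand-scanned tri locus is found with correct coordinates", {
  loci <- find_ssrs(c(r1 = "CCGAAGAAGAACC"))
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$start, 2L)
  expect_identical(loci$end, 11L)
  expect_identical(loci$canonical, "AAG")
  expect_identical(loci$class, "tri")
})

test_that("Ns break runs and empty reads yield empty results", {
  expect_identical(nrow(find_ssrs("AAAAANAAAAA")), 0L)
  expect_identical(nrow(find_ssrs("")), 0L)
  # run resumes cleanly after the N
  loci <- find_ssrs(paste0(strrep("A", 12), "N", strrep("T", 12)))
  expect_identical(nrow(loci), 2L)
  expect_identical(loci$total_len, c(12L, 12L))
})

test_that("smallest primitive unit wins and loci never overlap", {
  # a pure A run is mono, never reported again as di/tri
  loci <- find_ssrs(strrep("A", 24))
  expect_identical(loci$class, "mono")
  # adjacent different-motif runs are separate loci
  loci <- find_ssrs(paste0(strrep("AG", 6), strrep("CT", 6)))
  expect_true(all(diff(loci$start) >= loci$total_len[-nrow(loci)]))
  set.seed(42)
  for (i in 1:25) {
    loci <- find_ssrs(rand_dna(300))
    if (nrow(loci) > 1) {
      expect_true(all(loci$start[-1] >= loci$end[-nrow(loci)]))
    }
    expect_identical(loci$total_len, loci$unit_len * loci$n_units)
  }
})

test_that("scanner equals the brute-force enumerator on random sequences", {
  set.seed(202)
  # SSR-dense alphabet so thresholds are actually exercised
  for (i in 1:200) {
    s <- rand_dna(sample(20:200, 1), alphabet = c("A", "C", "A", "T"))
    got <- find_ssrs(s)
    want <- brute_force_ssrs(s)
    expect_identical(got$start, want$start, info = s)
    expect_identical(got$end, want$end, info = s)
    expect_identical(got$unit, want$unit, info = s)
  }
})

test_that("canonical motif multiset is strand-symmetric", {
  set.seed(7)
  reads <- vapply(1:30, function(i)
    rand_dna(400, alphabet = c("A", "C", "A", "T")), "")
  names(reads) <- paste0("r", 1:30, "F")
  fwd <- find_ssrs(reads)
  rev <- find_ssrs(stats::setNames(revcomp(reads), names(reads)))
  expect_identical(sort(fwd$canonical), sort(rev$canonical))
})

test_that("ssr_summary computes density, spacing and rankings", {
  expect_error(ssr_summary(data.frame(), 0))
  s0 <- ssr_summary(find_ssrs("ACGTACG"), 1000)
  expect_identical(s0$n_loci, 0L)
  expect_identical(s0$density_per_100kb, 0)
  expect_true(is.na(s0$spacing_kb))
  loci <- find_ssrs(c(a = strrep("A", 10), b = strrep("AC", 5),
                      c = strrep("A", 11)))
  s <- ssr_summary(loci, 1e5)
  expect_identical(s$n_loci, 3L)
  expect_equal(s$density_per_100kb, 3)
  expect_identical(s$class_counts[1:2], c(2L, 1L))
  # ranking: count descending, alphabetical tie-break
  expect_identical(s$motif_ranking$canonical, c("A", "AC"))
})
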