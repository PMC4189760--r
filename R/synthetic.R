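# Synthetic genome / BAC-library / BES generator with complete truth
# labels, so every downstream stage is testable at desk scale without the
# (undeposited) original reads.
#
# The stated world of the defaults is a plant BES survey: ~42% GC, ~19.6%
# of nucleotides repeat-derived (Class I >> Class II, Copia:Gypsy near
# 1:1), 10.8 perfect SSR loci per 100 kb with the published class mix,
# ~108 kb inserts (50-196 kb, ~87% above 90 kb), reads of 100-1,255 nt
# averaging ~587, ~0.17% organellar reads and a 5.4% exact-duplicate rate.
# Background sequence is i.i.d. with P(G)+P(C) = gc_fraction split evenly;
# planted features never overlap (rejection sampling with a small margin);
# one global seed feeds a named random stream per sub-step.

#' Construct a synthetic-survey specification
#'
#' All distributional defaults are the survey statistics listed above;
#' `genome_length` and `n_clones` default to desk scale.
#'
#' @param genome_length nuclear genome length in nt.
#' @param gc_fraction background GC proportion in `[0, 1]`.
#' @param repeat_families data.frame (`family`, `class_path`,
#'   `consensus_len`, `copies`); `NULL` builds the default four families
#'   scaled to `genome_length`.
#' @param ssr_density planted SSR loci per 100 kb.
#' @param ssr_class_mix six proportions (mono..hexa) summing to 1.
#' @param n_clones number of BAC clones.
#' @param insert_mean,insert_sd,insert_min,insert_max insert size in kb.
#' @param read_length_mean,read_sd,read_min,read_max read length in nt.
#' @param unpaired_fraction fraction of clones sequenced at one end only.
#' @param f_only_share of unpaired clones, share sequenced forward.
#' @param organellar_rate per-read probability of organellar origin.
#' @param organellar_mix named proportions over organelles.
#' @param duplicate_rate fraction of emitted reads that are planted exact
#'   duplicates (stand-in for the survey's redundancy, whose generative
#'   mechanism is unstated).
#' @param mutation_rate per-base substitution rate applied to planted
#'   repeat copies (0 keeps round-trips exact).
#' @param rearrangements list of edits for [derive_reference()], each
#'   `list(type, pos, len)` with `type` one of `"inversion"`,
#'   `"translocation"`, `"insertion"`, `"deletion"`.
#' @param seed integer master seed.
#' @return object of class `survey_spec`.
#' @export
survey_spec <- function(genome_length = 1e6,
                        gc_fraction = 0.419,
                        repeat_families = NULL,
                        ssr_density = 10.8,
                        ssr_class_mix = c(mono = 0.157, di = 0.177,
                                          tri = 0.125, tetra = 0.298,
                                          penta = 0.159, hexa = 0.084),
                        n_clones = 200,
                        insert_mean = 108, insert_sd = 16,
                        insert_min = 50, insert_max = 196,
                        read_length_mean = 587, read_sd = 190,
                        read_min = 100, read_max = 1255,
                        unpaired_fraction = 916 / 5974,
                        f_only_share = 512 / 916,
                        organellar_rate = 17 / 9698,
                        organellar_mix = c(chloroplast = 15 / 17,
                                           mitochondrial = 2 / 17),
                        duplicate_rate = 0.054,
                        mutation_rate = 0,
                        rearrangements = list(),
                        seed = 1L) {
  if (is.null(repeat_families)) {
    repeat_families <- default_repeat_families(genome_length)
  }
  spec <- structure(list(
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    repeat_families = repeat_families, ssr_density = ssr_density,
    ssr_class_mix = ssr_class_mix, n_clones = as.integer(n_clones),
    insert_mean = insert_mean, insert_sd = insert_sd,
    insert_min = insert_min, insert_max = insert_max,
    read_length_mean = read_length_mean, read_sd = read_sd,
    read_min = read_min, read_max = read_max,
    unpaired_fraction = unpaired_fraction, f_only_share = f_only_share,
    organellar_rate = organellar_rate, organellar_mix = organellar_mix,
    duplicate_rate = duplicate_rate, mutation_rate = mutation_rate,
    rearrangements = rearrangements, seed = as.integer(seed)
  ), class = "survey_spec")
  validate_survey_spec(spec)
  spec
}

default_repeat_families <- function(genome_length) {
  fam <- data.frame(
    family = c("synCopia1", "synGypsy1", "synLINE1", "synMuDR1"),
    class_path = c("ClassI/LTR/Copia", "ClassI/LTR/Gypsy",
                   "ClassI/LINE_SINE", "ClassII/DNA"),
    consensus_len = c(5000L, 5500L, 3000L, 2500L),
    # nucleotide fractions chosen to total ~19.6% with Copia:Gypsy ~ 1:1.3
    fraction = c(0.083, 0.106, 0.0045, 0.0025),
    stringsAsFactors = FALSE)
  fam$copies <- as.integer(round(fam$fraction * genome_length /
                                   fam$consensus_len))
  fam$fraction <- NULL
  fam
}

validate_survey_spec <- function(spec) {
  with(spec, {
    stopifnot(genome_length > 0, gc_fraction >= 0, gc_fraction <= 1,
              ssr_density >= 0, n_clones >= 0,
              insert_min <= insert_mean, insert_mean <= insert_max,
              insert_min > 0, read_min > 0, read_min <= read_max,
              unpaired_fraction >= 0, unpaired_fraction <= 1,
              organellar_rate >= 0, organellar_rate <= 1,
              duplicate_rate >= 0, duplicate_rate < 1,
              mutation_rate >= 0, mutation_rate < 1)
    if (abs(sum(ssr_class_mix) - 1) > 1e-9) {
      stop("ssr_class_mix must sum to 1")
    }
    if (length(ssr_class_mix) != 6L) {
      stop("ssr_class_mix needs six proportions (mono..hexa)")
    }
    if (nrow(repeat_families) &&
        any(repeat_families$consensus_len <= 0 | repeat_families$copies < 0)) {
      stop("repeat families need positive lengths and non-negative copies")
    }
  })
  invisible(spec)
}

#' Read / write a survey spec as JSON
#' @param path JSON file.
#' @return a `survey_spec`.
#' @export
read_survey_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$repeat_families <- if (!is.null(x$repeat_families))
    as.data.frame(x$repeat_families, stringsAsFactors = FALSE) else NULL
  x$rearrangements <- lapply(seq_len(NROW(x$rearrangements)), function(i)
    as.list(as.data.frame(x$rearrangements)[i, ]))
  x$ssr_class_mix <- unlist(x$ssr_class_mix)
  x$organellar_mix <- unlist(x$organellar_mix)
  do.call(survey_spec, x[!vapply(x, is.null, logical(1))])
}

#' @rdname read_survey_spec
#' @param spec a `survey_spec`.
#' @export
write_survey_spec <- function(spec, path) {
  x <- unclass(spec)
  # keep names of proportion vectors through the JSON round trip
  x$ssr_class_mix <- as.list(x$ssr_class_mix)
  x$organellar_mix <- as.list(x$organellar_mix)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @export
print.survey_spec <- function(x, ...) {
  cat(sprintf(paste0("Survey spec: %s nt genome (GC %.1f%%), %d clones, ",
                     "%d repeat families, %.1f SSR/100kb, seed %d\n"),
              format(x$genome_length, big.mark = ","),
              100 * x$gc_fraction, x$n_clones, nrow(x$repeat_families),
              x$ssr_density, x$seed))
  invisible(x)
}

# substitute bases at `rate`; substitutions always change the base
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in hit) {
    ch[i] <- alt[[ch[i]]][sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

# break every threshold-passing SSR in a sequence (used on repeat consensi
# and organellar genomes so that planted truth stays unambiguous)
strip_ssrs <- function(s) {
  for (iter in 1:50) {
    det <- ssr_scan_one(s)
    if (nrow(det) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(det))) {
      p <- det$start[i] + (det$end[i] - det$start[i]) %/% 2L + 1L  # 1-based
      excl <- unique(c(ch[p], ch[max(1L, p - 1L)],
                       ch[min(length(ch), p + 1L)]))
      ch[p] <- setdiff(c("A", "C", "G", "T"), excl)[1L]
    }
    s <- paste(ch, collapse = "")
  }
  stop("could not strip SSRs from sequence")
}

# rejection-sample `lens` non-overlapping placements within [0, G), with a
# safety margin between features; errors out when capacity is exceeded
place_intervals <- function(lens, genome_length, margin = 10L,
                            max_tries = 200L) {
  if (sum(lens) + 2L * margin * length(lens) > 0.6 * genome_length) {
    stop("planted content exceeds genome capacity: ",
         sum(lens), " nt requested in ", genome_length)
  }
  taken <- IRanges::IRanges()
  starts <- integer(length(lens))
  for (i in order(lens, decreasing = TRUE)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(genome_length - lens[i] + 1L, 1L) - 1L
      cand <- IRanges::IRanges(start = s + 1L - margin,
                               end = s + lens[i] + margin)
      if (length(IRanges::findOverlaps(cand, taken)) == 0L) {
        taken <- c(taken, cand)
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("planted content exceeds genome capacity: ",
                      "could not place a feature of ", lens[i], " nt")
  }
  starts
}

random_primitive_unit <- function(k) {
  repeat {
    u <- random_dna(k, 0.5)
    if (is_primitive(u)) return(u)
  }
}

#' Generate a synthetic source genome with planted truth
#'
#' Plants perfect SSR loci (meeting the miner's class thresholds) and
#' repeat-family copies into i.i.d. background sequence, then iteratively
#' breaks any background tandem repeat that the miner would report
#' (`sanitize = TRUE`) so the SSR truth table is exactly recoverable.
#' Organellar genomes (for contamination reads) are generated alongside.
#'
#' @param spec a `survey_spec`.
#' @param sanitize break spurious background SSRs (default `TRUE`).
#' @return object of class `bes_genome`: `genome` (string), `organellar`
#'   (named character), `consensi` (named character), `spec`, and `truth`
#'   with `ssr` and `repeats` data.frames (0-based half-open genome
#'   coordinates).
#' @export
generate_genome <- function(spec, sanitize = TRUE) {
  validate_survey_spec(spec)
  G <- spec$genome_length
  genome <- with_stream(spec$seed, "background",
                        random_dna(G, spec$gc_fraction))

  # repeat consensi, SSR-free so copies never add SSR loci
  fams <- spec$repeat_families
  consensi <- with_stream(spec$seed, "consensi", {
    out <- character(nrow(fams))
    for (i in seq_len(nrow(fams))) {
      out[i] <- strip_ssrs(random_dna(fams$consensus_len[i],
                                      spec$gc_fraction))
    }
    stats::setNames(out, if (nrow(fams))
      paste(fams$family, fams$class_path) else character(0))
  })

  # draw planted SSR loci
  n_ssr <- round(spec$ssr_density * G / 1e5)
  ssr <- with_stream(spec$seed, "ssr", {
    if (n_ssr == 0L) {
      data.frame(start = integer(0), end = integer(0), unit = character(0),
                 canonical = character(0), unit_len = integer(0),
                 n_units = integer(0), class = character(0),
                 stringsAsFactors = FALSE)
    } else {
      k <- sample.int(6L, n_ssr, replace = TRUE,
                      prob = spec$ssr_class_mix)
      unit <- vapply(k, random_primitive_unit, "")
      n_units <- integer(n_ssr)
      for (i in seq_len(n_ssr)) {
        n_units[i] <- switch(k[i], sample(10:20, 1L), sample(5:10, 1L),
                             sample(3:8, 1L), sample(3:6, 1L),
                             sample(3:5, 1L), sample(3:4, 1L))
      }
      data.frame(start = NA_integer_, end = NA_integer_, unit = unit,
                 canonical = canonical_motif(unit), unit_len = k,
                 n_units = n_units, class = SSR_CLASSES[k],
                 stringsAsFactors = FALSE)
    }
  })

  rep_truth <- data.frame(start = integer(0), end = integer(0),
                          family = character(0), class_path = character(0),
                          stringsAsFactors = FALSE)
  if (nrow(fams)) {
    rep_truth <- data.frame(
      start = NA_integer_,
      end = NA_integer_,
      family = rep(fams$family, fams$copies),
      class_path = rep(fams$class_path, fams$copies),
      consensus_len = rep(fams$consensus_len, fams$copies),
      stringsAsFactors = FALSE)
  }

  # place everything without overlap, then write features into background
  lens <- c(ssr$n_units * ssr$unit_len, rep_truth$consensus_len)
  starts <- with_stream(spec$seed, "placement",
                        place_intervals(lens, G))
  gch <- charToRaw(genome)
  if (nrow(ssr)) {
    ssr$start <- starts[seq_len(nrow(ssr))]
    ssr$end <- ssr$start + ssr$n_units * ssr$unit_len
    for (i in seq_len(nrow(ssr))) {
      piece <- strrep(ssr$unit[i], ssr$n_units[i])
      gch[(ssr$start[i] + 1L):ssr$end[i]] <- charToRaw(piece)
    }
  }
  if (nrow(rep_truth)) {
    rep_truth$start <- starts[nrow(ssr) + seq_len(nrow(rep_truth))]
    rep_truth$end <- rep_truth$start + rep_truth$consensus_len
    copies <- with_stream(spec$seed, "mutation", {
      idx <- match(paste(rep_truth$family, rep_truth$class_path),
                   names(consensi))
      vapply(seq_len(nrow(rep_truth)), function(i)
        mutate_seq(consensi[[idx[i]]], spec$mutation_rate), "")
    })
    for (i in seq_len(nrow(rep_truth))) {
      gch[(rep_truth$start[i] + 1L):rep_truth$end[i]] <-
        charToRaw(copies[i])
    }
    rep_truth$consensus_len <- NULL
  }
  genome <- rawToChar(gch)

  planted <- IRanges::IRanges(start = c(ssr$start, rep_truth$start) + 1L,
                              end = c(ssr$end, rep_truth$end))
  if (sanitize) {
    genome <- sanitize_genome(genome, ssr, planted)
  }

  organellar <- with_stream(spec$seed, "organellar", c(
    chloroplast_genome = strip_ssrs(random_dna(20000L, 0.37)),
    mitochondrial_genome = strip_ssrs(random_dna(30000L, 0.45))))

  structure(list(genome = genome, organellar = organellar,
                 consensi = consensi, spec = spec,
                 truth = list(ssr = ssr[order(ssr$start), , drop = FALSE],
                              repeats = rep_truth[order(rep_truth$start), ,
                                                  drop = FALSE])),
            class = "bes_genome")
}

# Iteratively repair the genome until the SSR miner reports exactly the
# planted truth: break spurious loci, break flank interference that
# extends or merges planted loci, and break *partial* right-extensions of
# planted runs (invisible to the floor-truncating miner on the forward
# strand, but they shift the detection phase on reverse-complemented
# reads).  Deterministic (no RNG).
sanitize_genome <- function(genome, ssr_truth, planted) {
  truth_key <- paste(ssr_truth$start, ssr_truth$end)
  for (iter in 1:40) {
    det <- ssr_scan_one(genome)
    det_key <- paste(det$start, det$end)
    spurious <- det[!(det_key %in% truth_key), , drop = FALSE]
    missing <- ssr_truth[!(truth_key %in% det_key), , drop = FALSE]
    ch <- strsplit(genome, "")[[1]]
    # partial right-extension: genome char just past a planted locus
    # continues the period without adding a full unit
    ext <- integer(0)
    for (i in seq_len(nrow(ssr_truth))) {
      b <- ssr_truth$end[i]                  # 0-based, so 1-based b + 1
      k <- ssr_truth$unit_len[i]
      if (b + 1L <= length(ch) && ch[b + 1L] == ch[b + 1L - k]) {
        ext <- c(ext, b + 1L)
      }
    }
    if (nrow(spurious) == 0L && nrow(missing) == 0L &&
        length(ext) == 0L) {
      return(genome)
    }
    fix_positions <- ext
    for (i in seq_len(nrow(spurious))) {
      cand <- (spurious$start[i] + 1L):spurious$end[i]  # 1-based
      inside <- IRanges::overlapsAny(
        IRanges::IRanges(start = cand, width = 1L), planted)
      cand <- cand[!inside]
      if (length(cand)) fix_positions <- c(fix_positions,
                                           cand[ceiling(length(cand) / 2)])
    }
    # a missing planted locus means something interferes at its flanks
    for (i in seq_len(nrow(missing))) {
      over <- det[det$start < missing$end[i] + 6L &
                    det$end > missing$start[i] - 6L, , drop = FALSE]
      for (j in seq_len(nrow(over))) {
        cand <- (over$start[j] + 1L):over$end[j]
        inside <- IRanges::overlapsAny(
          IRanges::IRanges(start = cand, width = 1L), planted)
        cand <- cand[!inside]
        if (length(cand)) fix_positions <- c(fix_positions, cand[1L])
      }
    }
    fix_positions <- unique(fix_positions)
    if (length(fix_positions) == 0L) {
      stop("sanitizer stuck: spurious SSR inside planted features")
    }
    for (p in fix_positions) {
      excl <- unique(c(ch[p], ch[max(1L, p - 1L)],
                       ch[min(length(ch), p + 1L)], "N"))
      ch[p] <- setdiff(c("A", "C", "G", "T"), excl)[1L]
    }
    genome <- paste(ch, collapse = "")
  }
  stop("sanitizer did not converge in 40 iterations")
}

#' Simulate a BAC library and its end reads
#'
#' Clone starts are uniform over the genome; insert lengths are truncated
#' normal within `[insert_min, insert_max]`.  The F read is the first L nt
#' of the insert on the forward strand, the R read the reverse complement
#' of the last L nt.  A fraction of clones emits only one end; organellar
#' reads replace nuclear ones at `organellar_rate`; exact duplicate reads
#' are appended at `duplicate_rate`.  Reads shorter than `read_min` after
#' truncation at insert edges are discarded and logged.
#'
#' @param genome a `bes_genome`, or a plain genome string.
#' @param spec a `survey_spec`; defaults to the genome's own.
#' @param organellar named character vector of organellar sequences
#'   (required when `organellar_rate > 0`; taken from the `bes_genome`
#'   when available).
#' @return object of class `bes_library`: `set` (a `bes_set`), `clones`
#'   (truth: `clone_id`, `start`, `insert_len`, `paired`, `ends`),
#'   `reads` (truth: `read_id`, `clone_id`, `end`, `gstart`, `gend`,
#'   `length`, `provenance`, `dup_of`), `n_discarded`, `genome`.
#' @export
simulate_library <- function(genome, spec = NULL, organellar = NULL) {
  if (inherits(genome, "bes_genome")) {
    spec <- spec %||% genome$spec
    organellar <- organellar %||% genome$organellar
    gobj <- genome
    genome <- genome$genome
  } else {
    gobj <- NULL
  }
  stopifnot(inherits(spec, "survey_spec"))
  G <- nchar(genome)
  if (G <= spec$insert_max * 1000) {
    stop("genome must be longer than insert_max")
  }
  if (spec$organellar_rate > 0 && is.null(organellar)) {
    stop("organellar_rate > 0 but no organellar sequences supplied")
  }
  n <- spec$n_clones
  ins <- with_stream(spec$seed, "inserts",
                     round(rtrunc_norm(n, spec$insert_mean, spec$insert_sd,
                                       spec$insert_min, spec$insert_max) *
                             1000))
  starts <- with_stream(spec$seed, "clone_starts", {
    vapply(ins, function(L) sample.int(G - L + 1L, 1L) - 1L, numeric(1))
  })
  ends_drawn <- with_stream(spec$seed, "unpaired", {
    unp <- stats::runif(n) < spec$unpaired_fraction
    forward_only <- stats::runif(n) < spec$f_only_share
    ifelse(unp, ifelse(forward_only, "F", "R"), "FR")
  })
  clone_id <- sprintf("C%05d", seq_len(n))
  reads <- list()
  rl_all <- with_stream(spec$seed, "read_lengths",
                        round(rtrunc_norm(2L * n, spec$read_length_mean,
                                          spec$read_sd, spec$read_min,
                                          spec$read_max)))
  for (i in seq_len(n)) {
    for (e in strsplit(ends_drawn[i], "")[[1]]) {
      L <- min(rl_all[2L * (i - 1L) + (e == "R") + 1L], ins[i])
      if (L < spec$read_min) next   # discarded, counted below
      if (e == "F") {
        gs <- starts[i]; ge <- starts[i] + L
        s <- substr(genome, gs + 1L, ge)
      } else {
        ge <- starts[i] + ins[i]; gs <- ge - L
        s <- revcomp(substr(genome, gs + 1L, ge))
      }
      reads[[length(reads) + 1L]] <- list(
        read_id = paste0(clone_id[i], e), clone_id = clone_id[i], end = e,
        gstart = gs, gend = ge, length = L, provenance = "nuclear",
        orient = if (e == "F") "+" else "-",
        dup_of = NA_character_, seq = s)
    }
  }
  n_expected <- sum(nchar(ends_drawn))
  n_discarded <- n_expected - length(reads)

  # organellar contamination: per-read Bernoulli replacement
  if (spec$organellar_rate > 0 && length(reads)) {
    reads <- with_stream(spec$seed, "organellar_reads", {
      hit <- which(stats::runif(length(reads)) < spec$organellar_rate)
      for (ri in hit) {
        org <- names(spec$organellar_mix)[
          sample.int(length(spec$organellar_mix), 1L,
                     prob = spec$organellar_mix)]
        oseq <- organellar[[grep(org, names(organellar))[1L]]]
        L <- reads[[ri]]$length
        L <- min(L, nchar(oseq))
        os <- sample.int(nchar(oseq) - L + 1L, 1L)
        reads[[ri]]$seq <- substr(oseq, os, os + L - 1L)
        reads[[ri]]$provenance <- org
        reads[[ri]]$gstart <- NA_integer_
        reads[[ri]]$gend <- NA_integer_
        reads[[ri]]$length <- L
      }
      reads
    })
  }

  # planted exact duplicates (new single-end pseudo-clones)
  if (spec$duplicate_rate > 0 && length(reads)) {
    reads <- with_stream(spec$seed, "duplicates", {
      n_base <- length(reads)
      d <- round(spec$duplicate_rate * n_base / (1 - spec$duplicate_rate))
      src <- sample.int(n_base, d, replace = TRUE)
      for (j in seq_len(d)) {
        o <- reads[[src[j]]]
        reads[[n_base + j]] <- list(
          read_id = sprintf("D%04dF", j), clone_id = sprintf("D%04d", j),
          end = "F", gstart = o$gstart, gend = o$gend, length = o$length,
          provenance = "duplicate", orient = o$orient,
          dup_of = o$read_id, seq = o$seq)
      }
      reads
    })
  }

  seqs <- stats::setNames(vapply(reads, `[[`, "", "seq"),
                          vapply(reads, `[[`, "", "read_id"))
  truth_reads <- data.frame(
    read_id = names(seqs),
    clone_id = vapply(reads, `[[`, "", "clone_id"),
    end = vapply(reads, `[[`, "", "end"),
    gstart = vapply(reads, function(x) as.integer(x$gstart), integer(1)),
    gend = vapply(reads, function(x) as.integer(x$gend), integer(1)),
    length = vapply(reads, function(x) as.integer(x$length), integer(1)),
    provenance = vapply(reads, `[[`, "", "provenance"),
    orient = vapply(reads, `[[`, "", "orient"),
    dup_of = vapply(reads, function(x) as.character(x$dup_of), character(1)),
    stringsAsFactors = FALSE)
  structure(list(
    set = bes_set(seqs, min_len = spec$read_min),
    clones = data.frame(clone_id = clone_id, start = as.integer(starts),
                        insert_len = as.integer(ins),
                        paired = ends_drawn == "FR", ends = ends_drawn,
                        stringsAsFactors = FALSE),
    reads = truth_reads,
    n_discarded = n_discarded,
    genome = gobj,
    spec = spec
  ), class = "bes_library")
}

#' @export
print.bes_library <- function(x, ...) {
  cat(sprintf("Synthetic BAC library: %d clones -> %d reads (%d discarded < read_min)\n",
              nrow(x$clones), nrow(x$reads), x$n_discarded))
  print(x$set)
  invisible(x)
}
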