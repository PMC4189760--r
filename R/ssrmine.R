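# Perfect-microsatellite mining.
#
# Detection follows the classical BES-survey convention: perfect tandem
# repeats with primitive unit length 1-6 nt; mononucleotide runs must span
# at least 10 nt, dinucleotides at least 5 repeat units, and tri- through
# hexanucleotides at least 3 units.  Motifs are grouped by cyclic rotation
# together with the reverse-complement strand, e.g. GA/AG/TC/CT all belong
# to the AG group and GAA/AAG/AGA/CTT/TTC/TCT to the AAG group.

SSR_CLASSES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

ssr_min_span <- function(unit_len) {
  # mono threshold is expressed in nucleotides, the rest in repeat units
  c(10L, 10L, 9L, 12L, 15L, 18L)[unit_len]
}

#' Canonical microsatellite motif
#'
#' Maps a primitive repeat unit to the representative of its equivalence
#' class: the lexicographically smallest string among all cyclic rotations
#' of the unit and of its reverse complement.  All `2 * nchar(unit)`
#' candidates map to the same canonical form, so e.g. `"GA"`, `"TC"` and
#' `"CT"` all canonicalize to `"AG"`.
#'
#' @param unit character vector of repeat units (1-6 nt, A/C/G/T only,
#'   primitive: not themselves a repetition of a shorter unit).
#' @return character vector of canonical motifs.
#' @examples
#' canonical_motif(c("GA", "TTC", "A"))
#' @export
canonical_motif <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    if (k < 1L || k > 6L) stop("motif length must be 1-6: ", u)
    if (grepl("[^ACGT]", u)) stop("motif must contain only A/C/G/T: ", u)
    if (!is_primitive(u)) stop("motif is not primitive: ", u)
    cand <- character(2L * k)
    rc <- revcomp(u)
    for (i in seq_len(k)) {
      cand[i] <- paste0(substr(u, i, k), substr(u, 1L, i - 1L))
      cand[k + i] <- paste0(substr(rc, i, k), substr(rc, 1L, i - 1L))
    }
    min(cand)
  }, character(1), USE.NAMES = FALSE)
}

# Scan one sequence for maximal perfect tandem runs.  Vectorized over
# positions (raw-byte comparisons + rle) so whole synthetic genomes can be
# scanned; only runs long enough to meet the class thresholds are expanded.
#
# Returns a data.frame of accepted loci with 0-based half-open coordinates.
ssr_scan_one <- function(seq) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_len = integer(0),
                      n_units = integer(0), stringsAsFactors = FALSE)
  if (n < 9L) return(empty)
  r <- charToRaw(seq)
  ok <- (r == charToRaw("A")) | (r == charToRaw("C")) |
        (r == charToRaw("G")) | (r == charToRaw("T"))
  cand <- vector("list", 6L)
  for (k in 1:6) {
    if (n < ssr_min_span(k)) next
    eq <- r[seq_len(n - k)] == r[(k + 1L):n] &
      ok[seq_len(n - k)] & ok[(k + 1L):n]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    # a TRUE run of length m spans m + k nucleotides
    min_m <- ssr_min_span(k) - k
    sel <- which(rl$values & rl$lengths >= min_m)
    if (length(sel) == 0L) next
    i <- starts[sel]                       # 1-based run start
    m <- rl$lengths[sel]
    n_units <- (m + k) %/% k
    keep <- n_units * k >= ssr_min_span(k)
    if (!any(keep)) next
    i <- i[keep]; n_units <- n_units[keep]
    unit <- substring(seq, i, i + k - 1L)
    prim <- vapply(unit, is_primitive, logical(1), USE.NAMES = FALSE)
    if (!any(prim)) next
    cand[[k]] <- data.frame(start = i[prim] - 1L,
                            end = i[prim] - 1L + n_units[prim] * k,
                            unit = unit[prim], unit_len = k,
                            n_units = n_units[prim],
                            stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  ssr_select(cand)
}

# Overlap resolution shared with the documentation: coinciding intervals are
# claimed by the smallest primitive unit; among distinct overlapping
# candidates the leftmost, then longest, wins; each nucleotide belongs to at
# most one reported locus.
ssr_select <- function(cand) {
  o <- order(cand$start, -(cand$end - cand$start), cand$unit_len)
  cand <- cand[o, , drop = FALSE]
  dup <- duplicated(cand[c("start", "end")])
  cand <- cand[!dup, , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Find perfect microsatellites
#'
#' Scans sequences for maximal perfect tandem repeats with primitive unit
#' length 1-6 nt meeting the survey thresholds (mono >= 10 nt, di >= 5
#' units, tri-hexa >= 3 units).  Ns break runs.  When runs for different
#' unit lengths coincide the smallest primitive unit wins, and among
#' distinct overlapping candidates the leftmost-then-longest wins, so each
#' nucleotide belongs to at most one reported locus.
#'
#' @param x a `bes_set`, or a (optionally named) character vector of
#'   uppercase DNA sequences.
#' @return data.frame with columns `read_id`, `start`, `end` (0-based
#'   half-open), `unit` (as observed), `canonical`, `unit_len`, `n_units`,
#'   `total_len`, `class`.
#' @examples
#' find_ssrs(c(r1 = "CCGAAGAAGAACC"))
#' @export
find_ssrs <- function(x) {
  seqs <- if (inherits(x, "bes_set")) x$seq else x
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) "seq" else paste0("seq", seq_along(seqs))
  }
  out <- lapply(seq_along(seqs), function(i) {
    df <- ssr_scan_one(seqs[[i]])
    if (nrow(df) == 0L) return(NULL)
    df$read_id <- names(seqs)[i]
    df
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_len = integer(0),
                      n_units = integer(0), read_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out$canonical <- if (nrow(out)) canonical_motif(out$unit) else character(0)
  out$total_len <- out$end - out$start
  out$class <- SSR_CLASSES[out$unit_len]
  rownames(out) <- NULL
  out[c("read_id", "start", "end", "unit", "canonical", "unit_len",
        "n_units", "total_len", "class")]
}

#' Summarize a set of microsatellite loci
#'
#' @param loci data.frame as returned by [find_ssrs()].
#' @param total_nt total number of nucleotides examined (> 0).
#' @return an object of class `ssr_summary`: per-class counts and
#'   percentages, density per 100 kb, mean spacing in kb (absent when no
#'   loci), and a per-canonical-motif ranking (count descending, then
#'   alphabetical).
#' @export
ssr_summary <- function(loci, total_nt) {
  stopifnot(total_nt > 0)
  counts <- table(factor(loci$class, levels = SSR_CLASSES))
  n <- nrow(loci)
  motifs <- if (n) {
    t <- as.data.frame(table(loci$canonical), stringsAsFactors = FALSE)
    names(t) <- c("canonical", "count")
    t <- t[order(-t$count, t$canonical), , drop = FALSE]
    rownames(t) <- NULL
    t
  } else {
    data.frame(canonical = character(0), count = integer(0))
  }
  structure(list(
    n_loci = n,
    class_counts = as.integer(counts),
    class_percent = if (n) 100 * as.integer(counts) / n else rep(0, 6L),
    classes = SSR_CLASSES,
    total_nt = total_nt,
    density_per_100kb = 1e5 * n / total_nt,
    spacing_kb = if (n) total_nt / n / 1000 else NA_real_,
    motif_ranking = motifs
  ), class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary: %d loci in %s nt (%.1f per 100 kb",
              x$n_loci, format(x$total_nt, big.mark = ","),
              x$density_per_100kb))
  if (!is.na(x$spacing_kb)) cat(sprintf(", one every %.2f kb", x$spacing_kb))
  cat(")\n")
  cls <- data.frame(class = x$classes, n = x$class_counts,
                    pct = round(x$class_percent, 1))
  print(cls, row.names = FALSE)
  invisible(x)
}
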