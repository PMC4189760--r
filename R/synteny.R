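# Paired-end microsynteny classification.
#
# Both ends of a BAC are aligned to a reference genome; each clone's pair
# of primary alignments is classified into one of six categories:
#   unmapped            - neither end aligned
#   SE                  - exactly one end aligned (single end)
#   PE_non_colocalized  - ends on different reference sequences
#   PE_gapped           - same reference, outer span outside [d_min, d_max]
#   PE_collinear        - span within limits, correct orientation
#   PE_rearranged       - span within limits, wrong orientation
# "Correct orientation" defaults to the standard paired-end FR
# configuration: ends on opposite strands facing inward, i.e. the
# forward-stranded end is the left one.  The span window defaults to the
# inclusive 15-350 kb used in BES surveys.

PAIR_CATEGORIES <- c("unmapped", "SE", "PE_non_colocalized",
                     "PE_collinear", "PE_rearranged", "PE_gapped")

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Load BAC-end alignments from a SAM file
#'
#' Parses the plain-text SAM dialect, keeping one primary alignment per
#' read: secondary (0x100) and supplementary (0x800) records are ignored,
#' and records with mapping quality below `min_mapq` are treated as
#' unmapped.  1-based SAM positions are converted to 0-based half-open
#' intervals using the CIGAR reference span.
#'
#' @param path SAM file.
#' @param min_mapq mapping-quality threshold (default 20).
#' @param end_pattern regex with one capture group parsing the end letter
#'   from the read name; reads that do not match are skipped with a
#'   warning.
#' @return data.frame of end alignments: `read_id`, `clone_id`, `end`,
#'   `rname`, `start`, `stop` (0-based half-open), `strand`, `mapq`,
#'   `mapped`.
#' @export
read_end_alignments <- function(path, min_mapq = 20,
                                end_pattern = "([FR])$") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(0), clone_id = character(0),
                      end = character(0), rname = character(0),
                      start = integer(0), stop = integer(0),
                      strand = character(0), mapq = integer(0),
                      mapped = logical(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  f <- f[keep]; qname <- qname[keep]; flag <- flag[keep]
  m <- regexpr(end_pattern, qname, perl = TRUE)
  ok <- m > 0L
  if (any(!ok)) {
    warning("skipping read(s) without parseable end suffix: ",
            paste(qname[!ok], collapse = ", "))
    f <- f[ok]; qname <- qname[ok]; flag <- flag[ok]; m <- m[ok]
  }
  if (anyDuplicated(qname)) {
    stop("multiple primary alignments for read(s): ",
         paste(unique(qname[duplicated(qname)]), collapse = ", "))
  }
  suf <- regmatches(qname, m)
  end <- sub(end_pattern, "\\1", suf, perl = TRUE)
  clone <- substr(qname, 1L, nchar(qname) - attr(m, "match.length"))
  rname <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  mapq <- as.integer(vapply(f, `[`, "", 5L))
  cigar <- vapply(f, `[`, "", 6L)
  mapped <- bitwAnd(flag, 0x4L) == 0L & rname != "*" & mapq >= min_mapq
  width <- cigar_ref_width(cigar)
  if (any(mapped & width == 0L)) {
    stop("mapped record with zero-length reference interval: ",
         paste(qname[mapped & width == 0L], collapse = ", "))
  }
  data.frame(read_id = qname, clone_id = clone, end = end,
             rname = ifelse(mapped, rname, NA_character_),
             start = ifelse(mapped, pos - 1L, NA_integer_),
             stop = ifelse(mapped, pos - 1L + width, NA_integer_),
             strand = ifelse(mapped,
                             ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+"),
                             NA_character_),
             mapq = mapq, mapped = mapped, stringsAsFactors = FALSE)
}

#' Classify one clone's end pair
#'
#' Decision rules, applied in order: (1) neither end mapped: `unmapped`;
#' (2) exactly one mapped: `SE`; (3) different references:
#' `PE_non_colocalized`; (4) same reference, outer span outside the
#' inclusive `[d_min, d_max]` window: `PE_gapped`; (5) within the window
#' with correct orientation: `PE_collinear`; (6) within the window,
#' wrong orientation: `PE_rearranged`.  The span is measured between the
#' outermost alignment coordinates (the implied insert span).
#'
#' @param f,r end alignments (one-row data.frames or lists with fields
#'   `mapped`, `rname`, `start`, `stop`, `strand`); either may be `NULL`
#'   for an end that was never sequenced.
#' @param d_min,d_max span window in bp (defaults 15,000 and 350,000,
#'   inclusive).
#' @param orientation `"fr"` (default: opposite strands, facing inward)
#'   or `"opposite"` (opposite strands only).
#' @return list: `category`, `rname`, `span_bp`, `orientation_ok`.
#' @export
classify_pair <- function(f, r, d_min = 15000, d_max = 350000,
                          orientation = c("fr", "opposite")) {
  orientation <- match.arg(orientation)
  fm <- !is.null(f) && isTRUE(f$mapped)
  rm_ <- !is.null(r) && isTRUE(r$mapped)
  if (!fm && !rm_) {
    return(list(category = "unmapped", rname = NA_character_,
                span_bp = NA_real_, orientation_ok = NA))
  }
  if (xor(fm, rm_)) {
    one <- if (fm) f else r
    return(list(category = "SE", rname = one$rname, span_bp = NA_real_,
                orientation_ok = NA))
  }
  for (a in list(f, r)) {
    if (a$stop <= a$start) stop("mapped record with zero-length interval")
  }
  if (f$rname != r$rname) {
    return(list(category = "PE_non_colocalized",
                rname = paste(f$rname, r$rname, sep = ","),
                span_bp = NA_real_, orientation_ok = NA))
  }
  span <- max(f$stop, r$stop) - min(f$start, r$start)
  opposite <- f$strand != r$strand
  left <- if (f$start <= r$start) f else r
  ok <- if (orientation == "fr") opposite && left$strand == "+" else opposite
  if (span < d_min || span > d_max) {
    return(list(category = "PE_gapped", rname = f$rname, span_bp = span,
                orientation_ok = ok))
  }
  list(category = if (ok) "PE_collinear" else "PE_rearranged",
       rname = f$rname, span_bp = span, orientation_ok = ok)
}

#' Classify every clone in an alignment table
#'
#' @param aln data.frame from [read_end_alignments()].
#' @inheritParams classify_pair
#' @return data.frame: `clone_id`, `category`, `rname`, `span_bp`,
#'   `strands`, one row per clone, ordered by clone id.
#' @export
classify_pairs <- function(aln, d_min = 15000, d_max = 350000,
                           orientation = c("fr", "opposite")) {
  orientation <- match.arg(orientation)
  clones <- sort(unique(aln$clone_id))
  rows <- lapply(clones, function(cl) {
    sub <- aln[aln$clone_id == cl, , drop = FALSE]
    f <- sub[sub$end == "F", , drop = FALSE]
    r <- sub[sub$end == "R", , drop = FALSE]
    f <- if (nrow(f)) as.list(f[1L, ]) else NULL
    r <- if (nrow(r)) as.list(r[1L, ]) else NULL
    cls <- classify_pair(f, r, d_min, d_max, orientation)
    strands <- paste(c(if (!is.null(f) && isTRUE(f$mapped)) f$strand,
                       if (!is.null(r) && isTRUE(r$mapped)) r$strand),
                     collapse = "/")
    data.frame(clone_id = cl, category = cls$category,
               rname = cls$rname, span_bp = cls$span_bp,
               strands = if (nzchar(strands)) strands else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Span between two reference coordinates, in kb
#'
#' @param pos_a,pos_b reference positions in bp (>= 0).
#' @return `abs(pos_a - pos_b) / 1000`, rounded to one decimal.
#' @examples
#' span_kb(15558, 130159)   # 114.6
#' @export
span_kb <- function(pos_a, pos_b) {
  stopifnot(all(pos_a >= 0), all(pos_b >= 0))
  round(abs(pos_a - pos_b) / 1000, 1)
}

#' Summarize pair categories
#'
#' @param classes data.frame from [classify_pairs()].
#' @return object of class `synteny_summary`: per-category counts in a
#'   fixed order plus the SE/PE totals (`n_matches` counts clones with at
#'   least one mapped end).
#' @export
synteny_summary <- function(classes) {
  counts <- table(factor(classes$category, levels = PAIR_CATEGORIES))
  n_pe <- sum(counts[c("PE_non_colocalized", "PE_collinear",
                       "PE_rearranged", "PE_gapped")])
  structure(list(category_counts = stats::setNames(as.integer(counts),
                                                   PAIR_CATEGORIES),
                 n_se = as.integer(counts[["SE"]]),
                 n_pe = as.integer(n_pe),
                 n_matches = as.integer(counts[["SE"]] + n_pe)),
            class = "synteny_summary")
}

#' @export
print.synteny_summary <- function(x, ...) {
  cat(sprintf("Microsynteny: %d positive matches (%d SE, %d PE)\n",
              x$n_matches, x$n_se, x$n_pe))
  for (cat_ in names(x$category_counts)) {
    cat(sprintf("  %-20s %d\n", cat_, x$category_counts[[cat_]]))
  }
  invisible(x)
}
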