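# Repeat-annotation accounting: parse RepeatMasker-style .out files (or a
# generic feature TSV), merge intervals, mask sequences, and compute the
# class-level nucleotide accounting and density.  A naive k-mer masker is
# included so the whole pipeline is testable without RepeatMasker.

REPEAT_CLASSES <- c("ClassI/LTR/Copia", "ClassI/LTR/Gypsy",
                    "ClassI/LTR/Unclassified", "ClassI/LINE_SINE",
                    "ClassII/DNA", "Unclassified", "SmallRNA",
                    "Satellite", "SimpleRepeat", "LowComplexity")

#' Default repeat class mapping
#'
#' Ordered regex -> class-path rules applied to the annotation's
#' class/family string (RepeatMasker conventions) and, failing that, to the
#' family name.  Extend or replace to adapt to other libraries.
#'
#' @return named character vector: names are regexes, values class paths.
#' @export
default_repeat_class_map <- function() {
  c("LTR/Copia|Copia"             = "ClassI/LTR/Copia",
    "LTR/Gypsy|Gypsy|DIRS"        = "ClassI/LTR/Gypsy",
    "^LTR"                        = "ClassI/LTR/Unclassified",
    "LINE|SINE"                   = "ClassI/LINE_SINE",
    "^DNA|^RC|Helitron|hAT|Harbinger|Mariner|MuDR|Tourist|Activator|Transposon" = "ClassII/DNA",
    "Simple_repeat|SimpleRepeat"  = "SimpleRepeat",
    "Low_complexity|LowComplexity" = "LowComplexity",
    "Satellite"                   = "Satellite",
    "RNA|SmallRNA"                = "SmallRNA")
}

map_repeat_class <- function(family, class_str, class_map) {
  out <- rep(NA_character_, length(family))
  for (i in seq_along(class_map)) {
    hit <- is.na(out) & (grepl(names(class_map)[i], class_str) |
                           grepl(names(class_map)[i], family))
    out[hit] <- class_map[[i]]
  }
  # verbatim class paths pass through unchanged
  direct <- is.na(out) & class_str %in% REPEAT_CLASSES
  out[direct] <- class_str[direct]
  if (anyNA(out)) {
    warning("unmappable repeat class string(s) assigned Unclassified: ",
            paste(unique(class_str[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- "Unclassified"
  }
  out
}

#' Read repeat annotations
#'
#' Two dialects: `"rm_out"` is the RepeatMasker `.out` layout
#' (whitespace-delimited after 3 header lines, 1-based inclusive query
#' coordinates, converted to 0-based half-open on read); `"tsv"` is a
#' generic tab-separated table with columns `read_id`, `start`, `end`
#' (already 0-based half-open), `family`, `class`, and optionally `score`.
#'
#' @param path annotation file.
#' @param dialect `"rm_out"` or `"tsv"`.
#' @param class_map see [default_repeat_class_map()].
#' @param min_score optional score cutoff; features below it are dropped
#'   and counted in the `n_dropped` attribute.
#' @return data.frame of features: `read_id`, `start`, `end`, `family`,
#'   `class_path`, `score`.
#' @export
read_repeat_annotations <- function(path, dialect = c("rm_out", "tsv"),
                                    class_map = default_repeat_class_map(),
                                    min_score = NULL) {
  dialect <- match.arg(dialect)
  empty <- data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      class_path = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (dialect == "rm_out") {
    lines <- readLines(path)
    if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(empty)
    f <- strsplit(lines, "\\s+")
    feats <- data.frame(
      read_id = vapply(f, `[`, "", 5L),
      start = as.integer(vapply(f, `[`, "", 6L)) - 1L,
      end = as.integer(vapply(f, `[`, "", 7L)),
      family = vapply(f, `[`, "", 10L),
      class_str = vapply(f, `[`, "", 11L),
      score = as.numeric(vapply(f, `[`, "", 1L)),
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) return(empty)
    feats <- data.frame(read_id = as.character(tab$read_id),
                        start = as.integer(tab$start),
                        end = as.integer(tab$end),
                        family = as.character(tab$family),
                        class_str = as.character(tab$class),
                        score = if ("score" %in% names(tab))
                          as.numeric(tab$score) else NA_real_,
                        stringsAsFactors = FALSE)
  }
  n_dropped <- 0L
  if (!is.null(min_score)) {
    drop <- !is.na(feats$score) & feats$score < min_score
    n_dropped <- sum(drop)
    feats <- feats[!drop, , drop = FALSE]
  }
  feats$class_path <- map_repeat_class(feats$family, feats$class_str,
                                       class_map)
  feats$class_str <- NULL
  stopifnot(all(feats$start < feats$end))
  rownames(feats) <- NULL
  attr(feats, "n_dropped") <- n_dropped
  feats
}

#' Write repeat features as generic TSV
#' @param features feature data.frame.
#' @param path output file.
#' @export
write_repeat_features <- function(features, path) {
  out <- data.frame(read_id = features$read_id, start = features$start,
                    end = features$end, family = features$family,
                    class = features$class_path, score = features$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mask repeat regions in a BES set
#'
#' @param set a `bes_set`.
#' @param features repeat features referencing reads in the set.
#' @param soft if `FALSE` (default) hard-mask with N, else lowercase.
#' @return a new `bes_set` with masked sequences.
#' @export
mask_repeats <- function(set, features, soft = FALSE) {
  stopifnot(inherits(set, "bes_set"))
  seqs <- set$seq
  for (id in unique(features$read_id)) {
    if (!id %in% names(seqs)) {
      warning("feature(s) for unknown read ignored: ", id)
      next
    }
    n <- nchar(seqs[[id]])
    fi <- features[features$read_id == id, , drop = FALSE]
    if (any(fi$start < 0L | fi$end > n)) {
      warning("feature out of bounds on ", id, "; clipped")
    }
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(fi$start, 0L) + 1L, end = pmin(fi$end, n)))
    s <- strsplit(seqs[[id]], "")[[1]]
    pos <- unlist(lapply(seq_along(ir), function(j)
      seq(IRanges::start(ir)[j], IRanges::end(ir)[j])))
    s[pos] <- if (soft) tolower(s[pos]) else "N"
    seqs[[id]] <- paste(s, collapse = "")
  }
  out <- set
  out$seq <- seqs
  out
}

# per-read union width of a set of intervals
union_nt <- function(feats) {
  if (nrow(feats) == 0L) return(0L)
  total <- 0L
  for (id in unique(feats$read_id)) {
    fi <- feats[feats$read_id == id, , drop = FALSE]
    total <- total + sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = fi$start + 1L, end = fi$end))))
  }
  total
}

#' Repeat-density report
#'
#' Class-level accounting of repeat features over a set of examined
#' nucleotides.  Per read, intervals are merged per class and overall
#' (union), so each nucleotide counts once overall; density is
#' `100 * |union| / total_nt`.  Element counts are raw feature counts.
#'
#' @param features repeat feature data.frame.
#' @param total_nt total nucleotides examined (> 0).
#' @return object of class `repeat_report`: per-class table (`class`,
#'   `n_elements`, `masked_nt`, `pct_nt`), `total_masked_nt`, `total_nt`,
#'   `density_percent`.
#' @export
repeat_report <- function(features, total_nt) {
  stopifnot(total_nt > 0)
  per_class <- data.frame(class = REPEAT_CLASSES,
                          n_elements = 0L, masked_nt = 0L,
                          stringsAsFactors = FALSE)
  for (i in seq_along(REPEAT_CLASSES)) {
    fi <- features[features$class_path == REPEAT_CLASSES[i], , drop = FALSE]
    per_class$n_elements[i] <- nrow(fi)
    per_class$masked_nt[i] <- union_nt(fi)
  }
  per_class$pct_nt <- 100 * per_class$masked_nt / total_nt
  total_masked <- union_nt(features)
  structure(list(per_class = per_class,
                 n_elements = nrow(features),
                 total_masked_nt = total_masked,
                 total_nt = total_nt,
                 density_percent = 100 * total_masked / total_nt),
            class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf("Repeat report: %d elements, %s of %s nt masked (%.2f%%)\n",
              x$n_elements, format(x$total_masked_nt, big.mark = ","),
              format(x$total_nt, big.mark = ","), x$density_percent))
  tab <- x$per_class
  tab$pct_nt <- round(tab$pct_nt, 2)
  print(tab[tab$n_elements > 0L, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Naive repeat-library search
#'
#' Self-contained substitute for an external repeat masker: exact k-mer
#' seeding of each read against both strands of every library consensus,
#' ungapped extension under a mismatch-fraction tolerance, reporting
#' maximal hits of at least `min_len` nt as features.  Intended for
#' synthetic-data round trips, not for production annotation.
#'
#' @param set a `bes_set`.
#' @param library either a FASTA path or a named character vector of
#'   consensus sequences; each name is `"family class_path"` (whitespace
#'   separated, class optional).
#' @param k seed length (>= 8).
#' @param min_len minimum reported hit length.
#' @param max_mismatch_frac mismatch tolerance of the extension (0 =
#'   exact).
#' @return feature data.frame as in [read_repeat_annotations()].
#' @export
naive_repeat_search <- function(set, library, k = 12L, min_len = 50L,
                                max_mismatch_frac = 0) {
  stopifnot(inherits(set, "bes_set"), k >= 8L)
  if (is.character(library) && length(library) == 1L && file.exists(library)) {
    lib <- Biostrings::readBStringSet(library)
    library <- stats::setNames(toupper(as.character(lib)), names(lib))
  }
  if (length(library) == 0L) stop("empty repeat library")
  fam <- sub("\\s.*$", "", names(library))
  cls <- ifelse(grepl("\\s", names(library)),
                sub("^\\S+\\s+", "", names(library)), "Unclassified")
  # index all library k-mers once: k-mer string -> (lib seq, strand, pos)
  km <- list()
  for (j in seq_along(library)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") library[[j]] else revcomp(library[[j]])
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      kms <- substring(s, starts, starts + k - 1L)
      km[[length(km) + 1L]] <- data.frame(kmer = kms, lib = j,
                                          strand = strand, pos = starts,
                                          stringsAsFactors = FALSE)
    }
  }
  km <- do.call(rbind, km)
  kmidx <- split(seq_len(nrow(km)), km$kmer)
  feats <- list()
  for (ri in seq_len(nrow(set$records))) {
    id <- set$records$read_id[ri]
    seq <- set$seq[[id]]
    L <- nchar(seq)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    rk <- substring(seq, starts, starts + k - 1L)
    sel <- which(rk %in% names(kmidx))
    if (length(sel) == 0L) next
    rows_per_seed <- kmidx[rk[sel]]
    rows <- unlist(rows_per_seed, use.names = FALSE)
    seeds <- data.frame(rp = rep(starts[sel], lengths(rows_per_seed)),
                        lib = km$lib[rows], strand = km$strand[rows],
                        lp = km$pos[rows], stringsAsFactors = FALSE)
    seeds$diag <- seeds$rp - seeds$lp
    seeds <- seeds[order(seeds$lib, seeds$strand, seeds$diag, seeds$rp), ,
                   drop = FALSE]
    key <- paste(seeds$lib, seeds$strand, seeds$diag)
    rchars <- charToRaw(seq)
    for (grp in split(seq_len(nrow(seeds)), key)) {
      g <- seeds[grp, , drop = FALSE]
      # consecutive k-mer hits on one diagonal collapse into exact blocks
      brk <- c(TRUE, diff(g$rp) != 1L)
      block <- cumsum(brk)
      for (b in unique(block)) {
        gb <- g[block == b, , drop = FALSE]
        r0 <- gb$rp[1L]; r1 <- gb$rp[nrow(gb)] + k - 1L  # 1-based inclusive
        libseq <- if (gb$strand[1L] == "+") library[[gb$lib[1L]]] else
          revcomp(library[[gb$lib[1L]]])
        lchars <- charToRaw(libseq)
        off <- gb$diag[1L]                  # rp - lp
        mm <- 0L; len <- r1 - r0 + 1L
        # extend left
        p <- r0 - 1L
        best0 <- r0; best1 <- r1; bestmm <- mm
        while (p >= 1L && p - off >= 1L) {
          mm <- mm + as.integer(rchars[p] != lchars[p - off])
          len <- len + 1L
          if (mm / len <= max_mismatch_frac) { best0 <- p; bestmm <- mm }
          if (mm / len > max_mismatch_frac + 0.25) break
          p <- p - 1L
        }
        r0 <- best0; mm <- bestmm; len <- best1 - best0 + 1L
        p <- r1 + 1L
        nl <- length(lchars)
        while (p <= L && p - off <= nl) {
          mm <- mm + as.integer(rchars[p] != lchars[p - off])
          len <- len + 1L
          if (mm / len <= max_mismatch_frac) best1 <- p
          if (mm / len > max_mismatch_frac + 0.25) break
          p <- p + 1L
        }
        if (best1 - r0 + 1L >= min_len) {
          feats[[length(feats) + 1L]] <- data.frame(
            read_id = id, start = r0 - 1L, end = best1,
            family = fam[gb$lib[1L]], class_path = cls[gb$lib[1L]],
            score = best1 - r0 + 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(feats) == 0L) {
    return(data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      class_path = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  feats <- do.call(rbind, feats)
  # merge per read/family duplicates arising from multiple seeds
  out <- list()
  for (keyv in unique(paste(feats$read_id, feats$family, feats$class_path,
                            sep = "\r"))) {
    parts <- strsplit(keyv, "\r")[[1]]
    fi <- feats[feats$read_id == parts[1L] & feats$family == parts[2L], ,
                drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = fi$start + 1L,
                                           end = fi$end))
    out[[length(out) + 1L]] <- data.frame(
      read_id = parts[1L], start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir), family = parts[2L], class_path = parts[3L],
      score = IRanges::width(ir), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}
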