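# Rearranged reference genome and microsynteny truth.
#
# derive_reference() applies a list of edits (inversion / translocation /
# insertion / deletion, in left-to-right coordinate order, non-overlapping
# footprints in source coordinates) to the synthetic source genome, then
# recomputes for every clone the category its end pair must receive under
# the classifier's rules, recording it as truth.  An end read maps iff its
# source interval lies wholly within one contiguously-mapped piece; reads
# crossing an edit boundary, falling in a deletion, or of organellar
# origin are recorded as unmapped (a real long-read aligner would produce
# split alignments there, which the classifier ignores anyway).
# Translocated segments are emitted as separate reference sequences, which
# is the simplest deterministic way to realize non-co-localized pairs.

validate_edits <- function(edits, G) {
  if (length(edits) == 0L) return(invisible(edits))
  types <- vapply(edits, `[[`, "", "type")
  pos <- vapply(edits, function(e) as.numeric(e$pos), numeric(1))
  len <- vapply(edits, function(e) as.numeric(e$len), numeric(1))
  stopifnot(all(types %in% c("inversion", "translocation", "insertion",
                             "deletion")),
            all(pos >= 0), all(len > 0))
  fp_end <- ifelse(types == "insertion", pos, pos + len)
  if (any(fp_end > G)) stop("edit exceeds genome length")
  o <- order(pos)
  if (any(fp_end[o][-length(o)] > pos[o][-1L])) {
    stop("overlapping edits are rejected")
  }
  invisible(edits[o])
}

#' Derive a rearranged reference genome with pair-category truth
#'
#' @param lib a `bes_library` (carries the source genome, clones and
#'   reads).
#' @param rearrangements list of edits `list(type, pos, len)`; defaults to
#'   the spec's.
#' @param d_min,d_max classification window in bp (inclusive).
#' @param orientation passed to [classify_pair()].
#' @return object of class `bes_reference`: `reference` (named character:
#'   `ref1` plus one sequence per translocated segment), `alignments`
#'   (per-read truth placements), `pair_truth` (`clone_id`, `category`,
#'   `rname`, `span_bp`), `edits`.
#' @export
derive_reference <- function(lib, rearrangements = NULL,
                             d_min = 15000, d_max = 350000,
                             orientation = "fr") {
  stopifnot(inherits(lib, "bes_library"))
  spec <- lib$spec
  genome <- if (inherits(lib$genome, "bes_genome")) lib$genome$genome
            else stop("library does not carry its source genome")
  G <- nchar(genome)
  edits <- validate_edits(rearrangements %||% spec$rearrangements, G)

  types <- vapply(edits, `[[`, "", "type")
  pos <- vapply(edits, function(e) as.integer(e$pos), integer(1))
  len <- vapply(edits, function(e) as.integer(e$len), integer(1))
  bnd <- sort(unique(c(0L, G, pos, ifelse(types == "insertion",
                                          pos, pos + len))))
  seg <- data.frame(s = bnd[-length(bnd)], e = bnd[-1L],
                    fate = "keep", trans = NA_integer_,
                    ref_start = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(edits)) {
    if (types[i] == "insertion") next
    hit <- seg$s >= pos[i] & seg$e <= pos[i] + len[i]
    seg$fate[hit] <- c(inversion = "invert", deletion = "delete",
                       translocation = "trans")[[types[i]]]
    if (types[i] == "translocation") seg$trans[hit] <- i
  }
  ins_at <- stats::setNames(len[types == "insertion"],
                            pos[types == "insertion"])
  ins_seq <- with_stream(spec$seed, "reference_insertions",
                         lapply(ins_at, function(L)
                           random_dna(L, spec$gc_fraction)))

  pieces <- character(0)
  offset <- 0L
  for (i in seq_len(nrow(seg))) {
    key <- as.character(seg$s[i])
    if (key %in% names(ins_at)) {
      pieces <- c(pieces, ins_seq[[key]])
      offset <- offset + ins_at[[key]]
    }
    if (seg$fate[i] %in% c("keep", "invert")) {
      s <- substr(genome, seg$s[i] + 1L, seg$e[i])
      if (seg$fate[i] == "invert") s <- revcomp(s)
      pieces <- c(pieces, s)
      seg$ref_start[i] <- offset
      offset <- offset + (seg$e[i] - seg$s[i])
    }
  }
  if (as.character(G) %in% names(ins_at)) {
    pieces <- c(pieces, ins_seq[[as.character(G)]])
  }
  reference <- c(ref1 = paste(pieces, collapse = ""))
  tr_idx <- unique(seg$trans[seg$fate == "trans"])
  for (ti in tr_idx) {
    segs <- seg[!is.na(seg$trans) & seg$trans == ti, , drop = FALSE]
    nm <- paste0("trans", which(tr_idx == ti))
    reference[nm] <- paste(substring(genome, segs$s + 1L, segs$e),
                           collapse = "")
    seg$ref_start[!is.na(seg$trans) & seg$trans == ti] <-
      cumsum(c(0L, segs$e - segs$s))[seq_len(nrow(segs))]
    seg$fate[!is.na(seg$trans) & seg$trans == ti] <- paste0("trans:", nm)
  }

  map_interval <- function(gs, ge, strand) {
    if (is.na(gs)) return(NULL)
    i <- findInterval(gs, seg$s)
    if (ge > seg$e[i]) return(NULL)              # crosses a boundary
    if (seg$fate[i] == "delete") return(NULL)
    if (seg$fate[i] == "invert") {
      list(rname = "ref1",
           start = seg$ref_start[i] + (seg$e[i] - ge),
           stop = seg$ref_start[i] + (seg$e[i] - gs),
           strand = if (strand == "+") "-" else "+")
    } else if (startsWith(seg$fate[i], "trans:")) {
      list(rname = sub("^trans:", "", seg$fate[i]),
           start = seg$ref_start[i] + (gs - seg$s[i]),
           stop = seg$ref_start[i] + (ge - seg$s[i]), strand = strand)
    } else {
      list(rname = "ref1",
           start = seg$ref_start[i] + (gs - seg$s[i]),
           stop = seg$ref_start[i] + (ge - seg$s[i]), strand = strand)
    }
  }

  rd <- lib$reads
  aln <- data.frame(read_id = rd$read_id, clone_id = rd$clone_id,
                    end = rd$end, rname = NA_character_,
                    start = NA_integer_, stop = NA_integer_,
                    strand = NA_character_, mapq = 60L, mapped = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rd))) {
    m <- map_interval(rd$gstart[i], rd$gend[i], rd$orient[i])
    if (!is.null(m)) {
      aln$rname[i] <- m$rname
      aln$start[i] <- m$start
      aln$stop[i] <- m$stop
      aln$strand[i] <- m$strand
      aln$mapped[i] <- TRUE
    }
  }

  clones <- sort(unique(aln$clone_id))
  pair_truth <- do.call(rbind, lapply(clones, function(cl) {
    sub <- aln[aln$clone_id == cl, , drop = FALSE]
    f <- sub[sub$end == "F", , drop = FALSE]
    r <- sub[sub$end == "R", , drop = FALSE]
    cls <- classify_pair(if (nrow(f)) as.list(f[1L, ]) else NULL,
                         if (nrow(r)) as.list(r[1L, ]) else NULL,
                         d_min, d_max, orientation)
    data.frame(clone_id = cl, category = cls$category, rname = cls$rname,
               span_bp = cls$span_bp, stringsAsFactors = FALSE)
  }))

  structure(list(reference = reference, alignments = aln,
                 pair_truth = pair_truth, edits = edits),
            class = "bes_reference")
}

#' Write truth alignments as a SAM file
#'
#' Emits one primary record per read with the truth placement from
#' [derive_reference()] (MAPQ 60, ungapped CIGAR), so the synteny stage
#' can be exercised end-to-end without an external aligner.
#'
#' @param ref a `bes_reference`.
#' @param path output SAM file.
#' @export
write_truth_sam <- function(ref, path) {
  stopifnot(inherits(ref, "bes_reference"))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$reference),
                   nchar(ref$reference)))
  a <- ref$alignments
  rows <- ifelse(
    a$mapped,
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
            a$read_id, ifelse(a$strand == "-", 16L, 0L), a$rname,
            a$start + 1L, a$mapq, a$stop - a$start),
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", a$read_id))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Expected per-read SSR loci of a synthetic library
#'
#' Intersects the planted genome-level SSR truth with each read's source
#' interval (mirroring coordinates for reverse reads) and re-applies the
#' class thresholds to the truncated spans, giving exactly the loci a
#' perfect miner must report on the reads.
#'
#' @param lib a `bes_library` built from a `bes_genome`.
#' @return data.frame matching [find_ssrs()] columns (minus `unit`, which
#'   depends on the truncation phase): `read_id`, `start`, `end`,
#'   `canonical`, `unit_len`, `n_units`, `total_len`, `class`.
#' @export
expected_read_ssrs <- function(lib) {
  stopifnot(inherits(lib, "bes_library"),
            inherits(lib$genome, "bes_genome"))
  truth <- lib$genome$truth$ssr
  rd <- lib$reads[!is.na(lib$reads$gstart), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rd))) {
    ov <- truth[truth$end > rd$gstart[i] & truth$start < rd$gend[i], ,
                drop = FALSE]
    for (j in seq_len(nrow(ov))) {
      a <- max(ov$start[j], rd$gstart[i])
      b <- min(ov$end[j], rd$gend[i])
      k <- ov$unit_len[j]
      n_tr <- (b - a) %/% k
      if (n_tr * k < ssr_min_span(k)) next
      rstart <- if (rd$orient[i] == "+") a - rd$gstart[i]
                else rd$gend[i] - b
      out[[length(out) + 1L]] <- data.frame(
        read_id = rd$read_id[i], start = rstart, end = rstart + n_tr * k,
        canonical = ov$canonical[j], unit_len = k, n_units = n_tr,
        total_len = n_tr * k, class = SSR_CLASSES[k],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), canonical = character(0),
                      unit_len = integer(0), n_units = integer(0),
                      total_len = integer(0), class = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$read_id, out$start), , drop = FALSE]
}

#' Expected per-read repeat intervals of a synthetic library
#'
#' @param lib a `bes_library` built from a `bes_genome`.
#' @param min_len drop truncated intervals shorter than this (match the
#'   masker's `min_len`).
#' @return data.frame: `read_id`, `start`, `end`, `family`, `class_path`.
#' @export
expected_read_repeats <- function(lib, min_len = 50L) {
  stopifnot(inherits(lib, "bes_library"),
            inherits(lib$genome, "bes_genome"))
  truth <- lib$genome$truth$repeats
  rd <- lib$reads[!is.na(lib$reads$gstart), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rd))) {
    ov <- truth[truth$end > rd$gstart[i] & truth$start < rd$gend[i], ,
                drop = FALSE]
    for (j in seq_len(nrow(ov))) {
      a <- max(ov$start[j], rd$gstart[i])
      b <- min(ov$end[j], rd$gend[i])
      if (b - a < min_len) next
      rstart <- if (rd$orient[i] == "+") a - rd$gstart[i]
                else rd$gend[i] - b
      out[[length(out) + 1L]] <- data.frame(
        read_id = rd$read_id[i], start = rstart, end = rstart + (b - a),
        family = ov$family[j], class_path = ov$class_path[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      class_path = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$read_id, out$start), , drop = FALSE]
}
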