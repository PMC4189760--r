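# BAC-end sequence IO and set-level QC.
#
# A BES set pairs forward (F) and reverse (R) end reads by clone ID, which
# is the read name with its trailing end suffix removed.  Reads shorter
# than the minimum acceptable size (100 bp by default) are excluded on
# load and counted.

#' Load BAC-end sequences from FASTA
#'
#' Reads a BES FASTA, uppercases sequences, validates characters against
#' the IUPAC alphabet, applies the minimum-length filter and builds the
#' clone pairing index.  The end label (F/R) is parsed from the read name
#' with `end_pattern`; names that do not match are kept with
#' `end = "unknown"` and a warning.
#'
#' @param path FASTA file.
#' @param min_len minimum read length in nt (default 100); shorter records
#'   are excluded and counted in `n_filtered`.
#' @param end_pattern regex with one capture group matching the end suffix
#'   at the end of the read name.
#' @return object of class `bes_set` with elements `records` (data.frame:
#'   `read_id`, `clone_id`, `end`, `length`), `seq` (named character),
#'   `total_nt`, `n_filtered`, `filtered_ids`.
#' @export
read_bes <- function(path, min_len = 100, end_pattern = "([FR])$") {
  if (file.size(path) == 0L) {
    return(bes_set(stats::setNames(character(0), character(0)),
                   min_len = min_len, end_pattern = end_pattern))
  }
  raw <- Biostrings::readBStringSet(path)
  bes_set(stats::setNames(as.character(raw), names(raw)),
          min_len = min_len, end_pattern = end_pattern)
}

#' Build a BES set from in-memory sequences
#'
#' @param seqs named character vector of DNA sequences (names are read
#'   ids, unique).
#' @inheritParams read_bes
#' @return a `bes_set`; see [read_bes()].
#' @export
bes_set <- function(seqs, min_len = 100, end_pattern = "([FR])$") {
  ids <- names(seqs)
  if (length(seqs) && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
    stop("every sequence must be named with a read id")
  }
  ids <- as.character(ids %||% character(0))
  ids <- sub("\\s.*$", "", ids)   # FASTA descriptions after first token
  if (anyDuplicated(ids)) {
    stop("duplicate read name(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(seqs))
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  len <- nchar(seqs)
  drop <- len < min_len
  filtered_ids <- ids[drop]
  seqs <- seqs[!drop]; ids <- ids[!drop]; len <- len[!drop]
  m <- regexpr(end_pattern, ids, perl = TRUE)
  has_end <- m > 0L
  if (any(!has_end) && length(ids)) {
    warning("could not parse end suffix for: ",
            paste(ids[!has_end], collapse = ", "), "; kept as end=unknown")
  }
  end <- rep("unknown", length(ids))
  clone <- ids
  if (any(has_end)) {
    suf <- regmatches(ids, m)
    # capture group 1 is the end letter; the suffix may be longer than it
    end[has_end] <- sub(end_pattern, "\\1", suf[has_end], perl = TRUE)
    clone[has_end] <- substr(ids[has_end], 1L, nchar(ids[has_end]) -
                               attr(m, "match.length")[has_end])
  }
  names(seqs) <- ids
  structure(list(
    records = data.frame(read_id = ids, clone_id = clone, end = end,
                         length = len, stringsAsFactors = FALSE),
    seq = seqs,
    total_nt = sum(len),
    n_filtered = sum(drop),
    filtered_ids = filtered_ids
  ), class = "bes_set")
}

#' Write a BES set to FASTA (wrapped at 80 columns)
#' @param set a `bes_set`.
#' @param path output file.
#' @export
write_bes <- function(set, path) {
  stopifnot(inherits(set, "bes_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(set$seq), path,
                              width = 80L)
  invisible(path)
}

#' @export
print.bes_set <- function(x, ...) {
  p <- bes_pairing(x)
  cat(sprintf("BES set: %d reads, %s nt (%d filtered < min length)\n",
              nrow(x$records), format(x$total_nt, big.mark = ","),
              x$n_filtered))
  cat(sprintf("  clones: %d paired, %d F-only, %d R-only\n",
              sum(p$has_F & p$has_R), sum(p$has_F & !p$has_R),
              sum(!p$has_F & p$has_R)))
  invisible(x)
}

#' Clone pairing index of a BES set
#'
#' @param set a `bes_set`.
#' @return data.frame with one row per clone: `clone_id`, `has_F`,
#'   `has_R`, `paired`.
#' @export
bes_pairing <- function(set) {
  stopifnot(inherits(set, "bes_set"))
  rec <- set$records
  clones <- unique(rec$clone_id)
  has_F <- clones %in% rec$clone_id[rec$end == "F"]
  has_R <- clones %in% rec$clone_id[rec$end == "R"]
  data.frame(clone_id = clones, has_F = has_F, has_R = has_R,
             paired = has_F & has_R, stringsAsFactors = FALSE)
}

#' Redundancy of a sequenced set
#'
#' Defined as the exact-duplicate fraction: `1 - n_distinct / n_total`
#' after uppercasing.  The original survey reports redundancy without
#' defining it; clustering at partial identity is deliberately out of
#' scope, so do not compare this number naively against tools that cluster.
#'
#' @param set a non-empty `bes_set`.
#' @return proportion in `[0, 1)`.
#' @export
redundancy <- function(set) {
  stopifnot(inherits(set, "bes_set"))
  n <- length(set$seq)
  if (n == 0L) stop("redundancy is undefined for an empty set")
  1 - length(unique(unname(set$seq))) / n
}

#' Screen reads for organellar origin from BLAST tabular hits
#'
#' A read is labelled organellar iff it has at least one hit with e-value
#' strictly below `evalue_max` to a subject whose name matches that
#' organelle's pattern; chloroplast takes precedence over mitochondrial on
#' conflict (a message is emitted).
#'
#' @param set a `bes_set`.
#' @param hits path to a 12-column BLAST tabular file, or a data.frame
#'   from [read_blast_tab()].
#' @param evalue_max e-value cutoff (default `1e-6`).
#' @param organelle_map named character vector of regexes matched against
#'   subject ids; names are the organelle labels.
#' @return named character vector over all reads in the set with values
#'   `"nuclear"`, `"chloroplast"` or `"mitochondrial"`.
#' @export
screen_organellar <- function(set, hits, evalue_max = 1e-6,
                              organelle_map = c(
                                chloroplast = "chloroplast|^cp",
                                mitochondrial = "mitochond|^mt")) {
  stopifnot(inherits(set, "bes_set"))
  if (is.character(hits)) hits <- read_blast_tab(hits)
  lab <- stats::setNames(rep("nuclear", nrow(set$records)),
                         set$records$read_id)
  if (nrow(hits) == 0L) return(lab)
  unknown <- !(hits$qseqid %in% names(lab))
  if (any(unknown)) {
    warning("hits for unknown read(s) ignored: ",
            paste(unique(hits$qseqid[unknown]), collapse = ", "))
    hits <- hits[!unknown, , drop = FALSE]
  }
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  # mitochondrial first so chloroplast overwrites it on conflict
  for (org in rev(names(organelle_map))) {
    sel <- grepl(organelle_map[[org]], hits$sseqid, ignore.case = TRUE)
    conflict <- names(lab) %in% hits$qseqid[sel] & lab != "nuclear"
    if (any(conflict)) {
      message("read(s) with hits to multiple organelles, chloroplast wins: ",
              paste(names(lab)[conflict], collapse = ", "))
    }
    lab[names(lab) %in% hits$qseqid[sel]] <- org
  }
  lab
}
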