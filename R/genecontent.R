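# Gene-content calls from BLASTX tabular output, species top-hit tallies,
# genome-wide coding extrapolation and GO-term accounting.
#
# Two e-value cutoffs coexist, as is common in BES surveys: a permissive
# one for the similarity search itself (1e-5) and a stricter one for
# annotation and the headline coding fraction (1e-6).  Both are exposed.

BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")

#' Read 12-column BLAST tabular output
#'
#' Malformed rows (wrong field count or non-numeric e-value/bitscore) are
#' skipped with a warning naming the line numbers.
#'
#' @param path BLAST `-outfmt 6` file.
#' @return data.frame with the twelve standard columns.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  empty <- stats::setNames(
    data.frame(character(0), character(0), numeric(0), integer(0),
               integer(0), integer(0), integer(0), integer(0), integer(0),
               integer(0), numeric(0), numeric(0),
               stringsAsFactors = FALSE), BLAST_COLS)
  if (length(lines) == 0L) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 12L
  ev <- suppressWarnings(as.numeric(vapply(f, function(x) x[11L] %||% NA_character_, "")))
  bs <- suppressWarnings(as.numeric(vapply(f, function(x) x[12L] %||% NA_character_, "")))
  bad <- bad | is.na(ev) | is.na(bs)
  if (any(bad)) {
    warning("skipping malformed BLAST row(s) at line(s): ",
            paste(which(bad), collapse = ", "))
  }
  f <- f[!bad]
  if (length(f) == 0L) return(empty)
  out <- data.frame(
    qseqid = vapply(f, `[`, "", 1L), sseqid = vapply(f, `[`, "", 2L),
    pident = as.numeric(vapply(f, `[`, "", 3L)),
    length = as.integer(vapply(f, `[`, "", 4L)),
    mismatch = as.integer(vapply(f, `[`, "", 5L)),
    gapopen = as.integer(vapply(f, `[`, "", 6L)),
    qstart = as.integer(vapply(f, `[`, "", 7L)),
    qend = as.integer(vapply(f, `[`, "", 8L)),
    sstart = as.integer(vapply(f, `[`, "", 9L)),
    send = as.integer(vapply(f, `[`, "", 10L)),
    evalue = ev[!bad], bitscore = bs[!bad],
    stringsAsFactors = FALSE)
  out
}

#' Call coding reads from BLAST hits
#'
#' A read is coding iff it has at least one hit with e-value strictly
#' below `evalue_max`.  The top hit is the minimum e-value, ties broken by
#' maximum bit score, then by file order (deterministic).
#'
#' @param hits data.frame from [read_blast_tab()] (or a path).
#' @param evalue_max annotation cutoff (default `1e-6`, strict `<`).
#' @param reads optional character vector of all read ids, so reads with
#'   no hits appear with `coding = FALSE`.
#' @return data.frame: `read_id`, `coding`, `top_subject`, `top_evalue`,
#'   `top_bitscore`.
#' @export
call_coding <- function(hits, evalue_max = 1e-6, reads = NULL) {
  if (is.character(hits)) hits <- read_blast_tab(hits)
  hits$.row <- seq_len(nrow(hits))
  pass <- hits[hits$evalue < evalue_max, , drop = FALSE]
  tops <- if (nrow(pass)) {
    o <- order(pass$evalue, -pass$bitscore, pass$.row)
    pass <- pass[o, , drop = FALSE]
    pass[!duplicated(pass$qseqid), , drop = FALSE]
  } else pass
  ids <- unique(c(reads, hits$qseqid))
  m <- match(ids, tops$qseqid)
  data.frame(read_id = ids,
             coding = !is.na(m),
             top_subject = tops$sseqid[m],
             top_evalue = tops$evalue[m],
             top_bitscore = tops$bitscore[m],
             stringsAsFactors = FALSE)
}

#' Species ranking of coding-read top hits
#'
#' @param calls data.frame from [call_coding()].
#' @param species_map subject -> species: a named character vector, a
#'   two-column data.frame (`subject`, `species`), or a path to a
#'   two-column TSV.  Subjects without a mapping fall in `"unknown"`.
#' @return data.frame `species`, `count`, `percent`, sorted by count
#'   descending with alphabetical tie-break.
#' @export
species_ranking <- function(calls, species_map) {
  coding <- calls[calls$coding, , drop = FALSE]
  if (nrow(coding) == 0L) {
    return(data.frame(species = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.character(species_map) && length(species_map) == 1L &&
      file.exists(species_map)) {
    tab <- utils::read.delim(species_map, header = FALSE,
                             stringsAsFactors = FALSE)
    species_map <- stats::setNames(tab[[2L]], tab[[1L]])
  }
  if (is.data.frame(species_map)) {
    species_map <- stats::setNames(species_map$species,
                                   species_map$subject)
  }
  sp <- unname(species_map[coding$top_subject])
  sp[is.na(sp)] <- "unknown"
  t <- as.data.frame(table(sp), stringsAsFactors = FALSE)
  names(t) <- c("species", "count")
  t <- t[order(-t$count, t$species), , drop = FALSE]
  t$percent <- 100 * t$count / sum(t$count)
  rownames(t) <- NULL
  t
}

#' Extrapolate genome-wide coding content
#'
#' `coding_mb` is the coding fraction times the genome size, truncated to
#' an integer (presentation-level choice that reproduces published-style
#' headline figures from their printed inputs); `gene_count` is
#' `coding_mb * 1000 / avg_gene_kb` rounded to the nearest thousand.
#'
#' @param n_coding,n_total coding and total read counts (`n_total > 0`).
#' @param genome_mb haploid genome size in Mb (> 0; default 1563).
#' @param avg_gene_kb assumed average gene length in kb (default 3.4).
#' @return list: `coding_fraction`, `coding_mb`, `gene_count`.
#' @examples
#' extrapolate_coding(940, 9698, 1563)   # ~151 Mb, 44,000 genes
#' @export
extrapolate_coding <- function(n_coding, n_total, genome_mb = 1563,
                               avg_gene_kb = 3.4) {
  stopifnot(n_total > 0, genome_mb > 0, avg_gene_kb > 0,
            n_coding >= 0, n_coding <= n_total)
  frac <- n_coding / n_total
  coding_mb <- trunc(frac * genome_mb)
  gene_count <- round(coding_mb * 1000 / avg_gene_kb / 1000) * 1000
  list(coding_fraction = frac, coding_mb = coding_mb,
       gene_count = gene_count)
}

GO_CATEGORIES <- c("molecular function", "biological process",
                   "cellular component")

#' GO-term accounting
#'
#' Counts (sequence, term) pairs: repeated terms across sequences count,
#' duplicates within one sequence are collapsed.  Categories are taken
#' from the table as supplied (no ontology traversal).  Per-term
#' percentages are relative to the number of sequences annotated in that
#' term's category.
#'
#' @param table data.frame with columns `read_id`, `go_id`, `category`
#'   (one of "molecular function", "biological process", "cellular
#'   component"), `term`; or a path
#'   to such a four-column TSV.
#' @return object of class `go_summary`.
#' @export
go_summary <- function(table) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  if (nrow(table) == 0L) {
    return(structure(list(n_terms = 0L, n_annotated = 0L,
                          mean_terms = NA_real_,
                          category_counts = stats::setNames(
                            rep(0L, 3L), GO_CATEGORIES),
                          term_table = data.frame()),
                     class = "go_summary"))
  }
  bad <- !(table$category %in% GO_CATEGORIES)
  if (any(bad)) {
    stop("unknown GO category in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(table$category[bad]), collapse = ", "))
  }
  table <- table[!duplicated(table[c("read_id", "go_id")]), , drop = FALSE]
  n_terms <- nrow(table)
  n_annotated <- length(unique(table$read_id))
  cat_counts <- vapply(GO_CATEGORIES, function(cc)
    length(unique(table$read_id[table$category == cc])), integer(1))
  term_table <- do.call(rbind, lapply(GO_CATEGORIES, function(cc) {
    sub <- table[table$category == cc, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    t <- as.data.frame(table(paste(sub$go_id, sub$term, sep = "\t")),
                       stringsAsFactors = FALSE)
    parts <- strsplit(t$Var1, "\t", fixed = TRUE)
    out <- data.frame(category = cc,
                      go_id = vapply(parts, `[`, "", 1L),
                      term = vapply(parts, `[`, "", 2L),
                      count = t$Freq,
                      percent = 100 * t$Freq / cat_counts[[cc]],
                      stringsAsFactors = FALSE)
    out[order(-out$count, out$term), , drop = FALSE]
  }))
  rownames(term_table) <- NULL
  structure(list(n_terms = n_terms, n_annotated = n_annotated,
                 mean_terms = n_terms / n_annotated,
                 category_counts = cat_counts,
                 term_table = term_table),
            class = "go_summary")
}

#' @export
print.go_summary <- function(x, ...) {
  cat(sprintf("GO summary: %d terms over %d annotated sequences", x$n_terms,
              x$n_annotated))
  if (!is.na(x$mean_terms)) cat(sprintf(" (mean %.1f terms/sequence)",
                                        x$mean_terms))
  cat("\n")
  for (cc in names(x$category_counts)) {
    cat(sprintf("  %s: %d sequences\n", cc, x$category_counts[[cc]]))
  }
  invisible(x)
}
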