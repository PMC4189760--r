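# Independent oracles and small fixture builders used across test files.

# Brute-force perfect-SSR enumerator: tests every (start, unit_len) pair,
# independent of the package's run-length scanner.  Thresholds: mono >= 10
# nt, di >= 5 units, tri..hexa >= 3 units.  Returns the same selection
# (coinciding intervals -> smallest unit; overlapping -> leftmost then
# longest) applied to brute-force candidates.
brute_force_ssrs <- function(seq) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  min_span <- c(10L, 10L, 9L, 12L, 15L, 18L)
  prim <- function(u) {
    k <- nchar(u)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L &&
          paste(rep(substr(u, 1L, d), k / d), collapse = "") == u) {
        return(FALSE)
      }
    }
    TRUE
  }
  cand <- list()
  for (s0 in seq_len(n)) {           # 1-based start
    for (k in 1:6) {
      if (s0 + k - 1L > n) next
      unit <- substr(seq, s0, s0 + k - 1L)
      if (grepl("[^ACGT]", unit) || !prim(unit)) next
      # left-maximality: the period must break just before s0
      if (s0 > 1L && s0 - 1L + k <= n && ch[s0 - 1L] == ch[s0 - 1L + k]) next
      n_units <- 1L
      while (s0 + (n_units + 1L) * k - 1L <= n &&
             substr(seq, s0 + n_units * k, s0 + (n_units + 1L) * k - 1L)
             == unit) {
        n_units <- n_units + 1L
      }
      if (n_units * k < min_span[k]) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = s0 - 1L, end = s0 - 1L + n_units * k, unit = unit,
        unit_len = k, n_units = n_units, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_len = integer(0),
                      n_units = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$unit_len), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand[c("start", "end")]), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# write a FASTA from a named character vector, return the path
write_fasta_tmp <- function(seqs, wrap = 60L) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))),
               con)
  }
  close(con)
  path
}

# minimal end-alignment stub for classify_pair tests
end_aln <- function(mapped = TRUE, rname = "chr1", start = 0,
                    stop = 600, strand = "+") {
  list(mapped = mapped, rname = rname, start = start, stop = stop,
       strand = strand)
}

# one-row SAM record
sam_line <- function(qname, flag, rname, pos, mapq, cigar) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
          qname, flag, rname, pos, mapq, cigar)
}
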