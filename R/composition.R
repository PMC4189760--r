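# GC-content computation.
#
# GC% = 100 * (G + C) / (A + C + G + T), with ambiguity codes and N
# excluded from both numerator and denominator; aggregates are pooled
# counts, never the mean of per-read percentages.  Whether the original
# survey excluded Ns is not documented anywhere we could find; excluding
# them is the only definition consistent with estimating genome
# composition from reads that contain ambiguous calls.

#' GC content of a set of sequences
#'
#' @param x a `bes_set` or a character vector of uppercase IUPAC DNA
#'   sequences (at least one, with at least one unambiguous base).
#' @return object of class `gc_report`: `gc_count`, `acgt_count`,
#'   `gc_percent`.
#' @examples
#' gc_content(c("ATGC", "NNNN"))
#' @export
gc_content <- function(x) {
  seqs <- if (inherits(x, "bes_set")) x$seq else x
  if (length(seqs) == 0L) stop("gc_content() needs at least one sequence")
  dss <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(dss, letters = c("A", "C", "G", "T"))
  gc <- sum(f[, "C"] + f[, "G"])
  acgt <- sum(f)
  if (acgt == 0) stop("no unambiguous A/C/G/T bases: GC content undefined")
  structure(list(gc_count = gc, acgt_count = acgt,
                 gc_percent = 100 * gc / acgt),
            class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  cat(sprintf("GC content: %.1f%% (%s G+C of %s unambiguous bases)\n",
              x$gc_percent, format(x$gc_count, big.mark = ","),
              format(x$acgt_count, big.mark = ",")))
  invisible(x)
}
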