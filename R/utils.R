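# Internal helpers shared across modules.

IUPAC_CHARS <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Reverse complement of character DNA sequences
#'
#' Operates on plain uppercase IUPAC character vectors, which is how
#' sequences travel between modules here.  Equivalent to
#' `Biostrings::reverseComplement()` on a `DNAStringSet` but without the
#' per-call S4 dispatch cost, which matters when called once per read.
#'
#' @param x character vector of IUPAC DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), "",
         USE.NAMES = FALSE)
}

# Derive a reproducible sub-seed for a named random stream.  One global
# integer seed plus a stream name gives every simulator sub-step its own
# stream, so adding a step never perturbs draws made by earlier steps.
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h) %% 2147483629L
}

with_stream <- function(seed, name, code) {
  withr::with_seed(stream_seed(seed, name), code)
}

# Random DNA string with P(G) + P(C) = gc, split evenly within each pair.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  rawToChar(charToRaw("ACGT")[idx])
}

# Truncated normal by rejection; degenerate sd = 0 collapses to the mean
# (clamped into [lo, hi]).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Is a motif primitive, i.e. not a whole-number repetition of a shorter unit?
is_primitive <- function(unit) {
  k <- nchar(unit)
  if (k <= 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(unit, 1L, d), k / d), collapse = "") == unit) {
      return(FALSE)
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
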