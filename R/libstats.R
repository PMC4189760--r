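# Library-level statistics: genome-equivalent coverage, Poisson recovery
# probability, insert-size summaries and organellar contamination rates.

#' Genome-equivalent coverage of a clone library
#'
#' `coverage = n_clones * mean_insert_mb / genome_mb`.  When an organellar
#' screen has run, pass the organellar-excluded clone count.
#'
#' @param n_clones number of (nuclear) clones (> 0).
#' @param mean_insert_mb mean insert size in Mb (> 0).
#' @param genome_mb haploid genome size in Mb (> 0).
#' @return genome equivalents (exact ratio; round to 2 decimals for
#'   display).
#' @examples
#' bac_coverage(82903, 0.108, 1563)   # 5.73
#' @export
bac_coverage <- function(n_clones, mean_insert_mb, genome_mb) {
  stopifnot(n_clones > 0, mean_insert_mb > 0, genome_mb > 0)
  n_clones * mean_insert_mb / genome_mb
}

#' Probability of recovering a single-copy locus
#'
#' Under Poisson sampling of clones, `P = 1 - exp(-coverage)`.
#'
#' @param coverage genome equivalents (>= 0).
#' @return probability in `[0, 1)`.
#' @export
p_single_copy <- function(coverage) {
  stopifnot(all(coverage >= 0))
  1 - exp(-coverage)
}

#' Insert-size summary
#'
#' @param sizes_kb insert sizes in kb (all > 0).
#' @param threshold_kb report the fraction strictly greater than this
#'   (default 90 kb).
#' @return list: `n`, `mean_kb`, `min_kb`, `max_kb`, `frac_gt_threshold`,
#'   `threshold_kb`.
#' @export
insert_summary <- function(sizes_kb, threshold_kb = 90) {
  if (length(sizes_kb) == 0L) stop("insert_summary() needs >= 1 size")
  if (any(sizes_kb <= 0)) stop("insert sizes must be positive")
  list(n = length(sizes_kb), mean_kb = mean(sizes_kb),
       min_kb = min(sizes_kb), max_kb = max(sizes_kb),
       frac_gt_threshold = mean(sizes_kb > threshold_kb),
       threshold_kb = threshold_kb)
}

#' Contamination rate as a percentage
#'
#' @param n_hits clones (or reads) flagged for one organelle.
#' @param n_clones total clones (> 0, `n_hits <= n_clones`).
#' @return percentage `100 * n_hits / n_clones`.
#' @examples
#' contamination_rate(36, 82944)   # 0.0434 -> printed 0.04
#' @export
contamination_rate <- function(n_hits, n_clones) {
  if (n_clones <= 0) stop("n_clones must be positive")
  stopifnot(n_hits >= 0, n_hits <= n_clones)
  100 * n_hits / n_clones
}

#' Assemble library statistics
#'
#' Convenience wrapper producing the full statistics block.  Coverage uses
#' the organellar-excluded clone count when organellar hit counts are
#' supplied (`exclude_organellar = TRUE`), otherwise all clones.
#'
#' @param n_clones total clones in the library.
#' @param insert_sizes_kb sampled insert sizes in kb.
#' @param genome_mb haploid genome size in Mb.
#' @param n_chloroplast,n_mitochondrial organellar clone counts.
#' @param exclude_organellar exclude organellar clones from coverage.
#' @param threshold_kb passed to [insert_summary()].
#' @return object of class `library_stats`.
#' @export
library_stats <- function(n_clones, insert_sizes_kb, genome_mb,
                          n_chloroplast = 0L, n_mitochondrial = 0L,
                          exclude_organellar = TRUE,
                          threshold_kb = 90) {
  ins <- insert_summary(insert_sizes_kb, threshold_kb)
  n_nuclear <- if (exclude_organellar)
    n_clones - n_chloroplast - n_mitochondrial else n_clones
  cov <- bac_coverage(n_nuclear, ins$mean_kb / 1000, genome_mb)
  structure(list(
    n_clones = n_clones, n_nuclear = n_nuclear,
    insert = ins, genome_mb = genome_mb,
    coverage = cov, p_single_copy = p_single_copy(cov),
    contamination_pct = c(
      chloroplast = contamination_rate(n_chloroplast, n_clones),
      mitochondrial = contamination_rate(n_mitochondrial, n_clones))
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("Library: %s clones (%s nuclear), genome %s Mb\n",
              format(x$n_clones, big.mark = ","),
              format(x$n_nuclear, big.mark = ","),
              format(x$genome_mb, big.mark = ",")))
  cat(sprintf("  inserts: mean %.0f kb [%.0f, %.0f], %.0f%% > %g kb\n",
              x$insert$mean_kb, x$insert$min_kb, x$insert$max_kb,
              100 * x$insert$frac_gt_threshold, x$insert$threshold_kb))
  cat(sprintf("  coverage: %.2f genome equivalents; P(single-copy locus) = %.3f%%\n",
              x$coverage, 100 * x$p_single_copy))
  cat(sprintf("  contamination: chloroplast %.3g%%, mitochondrial %.3g%%\n",
              x$contamination_pct[["chloroplast"]],
              x$contamination_pct[["mitochondrial"]]))
  invisible(x)
}
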