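# Survey orchestrator: wires QC, GC, SSR mining, repeat accounting,
# masking, gene content, library statistics and microsynteny into one
# reproducible run driven by a single structured (JSON) config.
#
# Stage order is fixed and mirrors standard BES practice: SSR search runs
# on the unmasked reads (before repeat masking), and the gene-content
# stage consumes hits computed after masking.  Every stage is a pure
# function of (inputs, config); the orchestrator adds no hidden state, so
# a rerun with identical inputs is byte-identical.

#' Default run configuration
#'
#' @return named list of every tunable with its default: `min_len` 100 nt,
#'   `evalue_search` 1e-5, `evalue_annot` 1e-6, `d_min`/`d_max` 15/350 kb,
#'   `min_mapq` 20, `genome_mb` 1563, `avg_gene_kb` 3.4, naive-masker
#'   `k` 16 / `repeat_min_len` 50 / `max_mismatch_frac` 0.05.
#' @export
default_run_config <- function() {
  list(min_len = 100, end_pattern = "([FR])$",
       evalue_search = 1e-5, evalue_annot = 1e-6,
       d_min = 15000, d_max = 350000, min_mapq = 20,
       genome_mb = 1563, avg_gene_kb = 3.4,
       k = 16, repeat_min_len = 50, max_mismatch_frac = 0.05,
       insert_mean_kb = 108)
}

#' Read a run configuration from JSON
#'
#' File values override built-in defaults; unknown keys are kept (and
#' logged) so stage-specific extensions can ride along.
#'
#' @param path JSON config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_run_config(), cfg)
}

#' Run the full BES survey
#'
#' Executes every stage whose inputs are present in `config`; stages with
#' missing optional inputs are reported as `"skipped"`.  Input paths:
#' `fasta` (required), `repeat_annotations` (RepeatMasker .out) or
#' `repeat_library` (FASTA for the naive masker), `organellar_hits` and
#' `blast_hits` (BLAST tabular), `species_map` (TSV), `go_table` (TSV),
#' `sam` (named list of SAM paths, one per reference genome), `n_clones`
#' and `insert_sizes_kb` for the library block.
#'
#' @param config named list (see [default_run_config()]) or a JSON path.
#' @param out_dir optional output directory; when given, every block is
#'   written as TSV plus a machine-readable `report.json`.
#' @return object of class `survey_report`.
#' @export
run_survey <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_run_config(), config)
  if (is.null(config$fasta)) stop("config$fasta is required")
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  say("stage qc: loading %s (min_len=%d)", config$fasta, config$min_len)
  set <- read_bes(config$fasta, min_len = config$min_len,
                  end_pattern = config$end_pattern)
  pairing <- bes_pairing(set)
  qc <- list(n_reads = nrow(set$records), total_nt = set$total_nt,
             n_filtered = set$n_filtered,
             mean_length = set$total_nt / max(1L, nrow(set$records)),
             n_clones_seen = nrow(pairing),
             n_paired = sum(pairing$paired),
             redundancy = if (nrow(set$records)) redundancy(set) else NA)

  screen <- NULL
  if (!is.null(config$organellar_hits)) {
    say("stage screen: %s", config$organellar_hits)
    lab <- screen_organellar(set, config$organellar_hits,
                             evalue_max = config$evalue_annot)
    screen <- as.list(table(lab))
  }

  say("stage gc")
  gc_all <- gc_content(set)

  say("stage ssr")
  loci <- find_ssrs(set)
  ssr <- ssr_summary(loci, set$total_nt)

  repeats <- NULL
  features <- NULL
  if (!is.null(config$repeat_annotations)) {
    say("stage repeats: annotations %s", config$repeat_annotations)
    features <- read_repeat_annotations(config$repeat_annotations,
                                        dialect = config$repeat_dialect %||% "rm_out")
  } else if (!is.null(config$repeat_library)) {
    say("stage repeats: naive search against %s (k=%d)",
        config$repeat_library, config$k)
    features <- naive_repeat_search(set, config$repeat_library,
                                    k = config$k,
                                    min_len = config$repeat_min_len,
                                    max_mismatch_frac = config$max_mismatch_frac)
  }
  masked_set <- set
  if (!is.null(features)) {
    repeats <- repeat_report(features, set$total_nt)
    say("stage mask: %d features", nrow(features))
    masked_set <- mask_repeats(set, features)
  }

  genes <- NULL
  gc_genic <- NULL
  if (!is.null(config$blast_hits)) {
    say("stage genes: %s (evalue < %g)", config$blast_hits,
        config$evalue_annot)
    calls <- call_coding(config$blast_hits,
                         evalue_max = config$evalue_annot,
                         reads = set$records$read_id)
    n_coding <- sum(calls$coding)
    genes <- list(calls = calls, n_coding = n_coding,
                  n_total = nrow(set$records),
                  extrapolation = extrapolate_coding(
                    n_coding, nrow(set$records), config$genome_mb,
                    config$avg_gene_kb))
    if (!is.null(config$species_map)) {
      genes$species <- species_ranking(calls, config$species_map)
    }
    if (n_coding > 0) {
      gc_genic <- gc_content(set$seq[calls$read_id[calls$coding]])
    }
  }

  go <- NULL
  if (!is.null(config$go_table)) {
    say("stage go: %s", config$go_table)
    go <- go_summary(config$go_table)
  }

  lib <- NULL
  if (!is.null(config$n_clones)) {
    say("stage libstats")
    sizes <- config$insert_sizes_kb %||% config$insert_mean_kb
    lib <- library_stats(
      n_clones = config$n_clones, insert_sizes_kb = sizes,
      genome_mb = config$genome_mb,
      n_chloroplast = config$n_chloroplast %||% 0L,
      n_mitochondrial = config$n_mitochondrial %||% 0L)
  }

  synteny <- NULL
  if (!is.null(config$sam) && length(config$sam)) {
    synteny <- list()
    for (refname in names(config$sam)) {
      say("stage synteny: %s -> %s", refname, config$sam[[refname]])
      aln <- read_end_alignments(config$sam[[refname]],
                                 min_mapq = config$min_mapq,
                                 end_pattern = config$end_pattern)
      cls <- classify_pairs(aln, d_min = config$d_min,
                            d_max = config$d_max)
      synteny[[refname]] <- list(classes = cls,
                                 summary = synteny_summary(cls))
    }
  } else {
    say("stage synteny: skipped (no SAM inputs)")
  }

  report <- structure(list(
    qc = qc, screen = screen %||% "skipped", gc = gc_all,
    gc_genic = gc_genic, ssr = ssr, ssr_loci = loci,
    repeats = repeats %||% "skipped", genes = genes %||% "skipped",
    go = go %||% "skipped", library = lib %||% "skipped",
    synteny = synteny %||% "skipped",
    masked_set = masked_set, config = config, log = log
  ), class = "survey_report")
  if (!is.null(out_dir)) write_survey_report(report, out_dir)
  report
}

#' Write a survey report to disk
#'
#' Emits one TSV per block plus a machine-readable `report.json` (and the
#' run log).  Output is a pure function of the report, so identical runs
#' produce byte-identical files.
#'
#' @param report a `survey_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_survey_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  kv <- function(x) data.frame(key = names(x),
                               value = vapply(x, function(v)
                                 paste(format(v, digits = 10),
                                       collapse = ","), ""))
  w(kv(report$qc), "qc.tsv")
  w(data.frame(gc_percent = report$gc$gc_percent,
               gc_count = report$gc$gc_count,
               acgt_count = report$gc$acgt_count), "gc.tsv")
  w(report$ssr_loci, "ssr_loci.tsv")
  w(data.frame(class = report$ssr$classes, count = report$ssr$class_counts,
               percent = report$ssr$class_percent), "ssr_classes.tsv")
  if (inherits(report$repeats, "repeat_report")) {
    w(report$repeats$per_class, "repeat_classes.tsv")
  }
  if (is.list(report$genes) && !is.null(report$genes$calls)) {
    w(report$genes$calls, "coding_calls.tsv")
  }
  if (is.list(report$synteny)) {
    for (refname in names(report$synteny)) {
      w(report$synteny[[refname]]$classes,
        paste0("synteny_", refname, ".tsv"))
    }
  }
  json <- survey_report_json(report)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

survey_report_json <- function(report) {
  list(
    qc = report$qc,
    gc_percent = report$gc$gc_percent,
    gc_genic_percent = if (!is.null(report$gc_genic))
      report$gc_genic$gc_percent else NULL,
    ssr = list(n_loci = report$ssr$n_loci,
               density_per_100kb = report$ssr$density_per_100kb,
               spacing_kb = report$ssr$spacing_kb,
               class_counts = stats::setNames(
                 as.list(report$ssr$class_counts), report$ssr$classes)),
    repeats = if (inherits(report$repeats, "repeat_report"))
      list(density_percent = report$repeats$density_percent,
           total_masked_nt = report$repeats$total_masked_nt) else "skipped",
    genes = if (is.list(report$genes))
      list(n_coding = report$genes$n_coding,
           coding_mb = report$genes$extrapolation$coding_mb,
           gene_count = report$genes$extrapolation$gene_count)
      else "skipped",
    go = if (inherits(report$go, "go_summary"))
      list(n_terms = report$go$n_terms,
           n_annotated = report$go$n_annotated,
           mean_terms = report$go$mean_terms) else "skipped",
    library = if (inherits(report$library, "library_stats"))
      list(coverage = report$library$coverage,
           p_single_copy = report$library$p_single_copy) else "skipped",
    synteny = if (is.list(report$synteny))
      lapply(report$synteny, function(s)
        as.list(s$summary$category_counts)) else "skipped")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("== BES survey report ==\n")
  cat(sprintf("reads: %d (%s nt, %d filtered); redundancy %.3f\n",
              x$qc$n_reads, format(x$qc$total_nt, big.mark = ","),
              x$qc$n_filtered, x$qc$redundancy))
  print(x$gc)
  print(x$ssr)
  if (inherits(x$repeats, "repeat_report")) print(x$repeats)
  if (is.list(x$genes)) {
    cat(sprintf("coding: %d of %d reads (%.2f%%) -> %d Mb, ~%d genes\n",
                x$genes$n_coding, x$genes$n_total,
                100 * x$genes$n_coding / x$genes$n_total,
                x$genes$extrapolation$coding_mb,
                x$genes$extrapolation$gene_count))
  }
  if (inherits(x$go, "go_summary")) print(x$go)
  if (inherits(x$library, "library_stats")) print(x$library)
  if (is.list(x$synteny)) {
    for (refname in names(x$synteny)) {
      cat(sprintf("-- synteny vs %s --\n", refname))
      print(x$synteny[[refname]]$summary)
    }
  }
  invisible(x)
}

#' Simulate a complete survey input set on disk
#'
#' Generates genome, library, reads, truth tables, a rearranged reference
#' with truth SAM, and a ready-to-run JSON config in `out_dir`, then
#' returns the paths.  Truth tables use 0-based half-open coordinates.
#'
#' @param spec a `survey_spec`.
#' @param out_dir output directory.
#' @return list with `config` (path) and the generated objects.
#' @export
simulate_survey <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(spec)
  lib <- simulate_library(gen)
  ref <- derive_reference(lib)
  paths <- list(
    fasta = file.path(out_dir, "bes.fasta"),
    organellar = file.path(out_dir, "organellar.fasta"),
    repeat_library = file.path(out_dir, "repeat_library.fasta"),
    sam = file.path(out_dir, "truth.sam"),
    organellar_hits = file.path(out_dir, "organellar_hits.tsv"))
  write_bes(lib$set, paths$fasta)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(gen$organellar), paths$organellar, width = 80L)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(gen$consensi), paths$repeat_library,
    width = 80L)
  write_truth_sam(ref, paths$sam)
  org <- lib$reads[lib$reads$provenance %in%
                     c("chloroplast", "mitochondrial"), , drop = FALSE]
  hits <- if (nrow(org)) {
    data.frame(qseqid = org$read_id,
               sseqid = paste0(org$provenance, "_genome"),
               pident = 100, length = org$length, mismatch = 0L,
               gapopen = 0L, qstart = 1L, qend = org$length, sstart = 1L,
               send = org$length, evalue = 1e-80, bitscore = 500)
  } else {
    data.frame()
  }
  utils::write.table(hits, paths$organellar_hits, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(gen$truth$ssr, file.path(out_dir, "truth_ssr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$truth$repeats,
                     file.path(out_dir, "truth_repeats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lib$clones, file.path(out_dir, "truth_clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lib$reads, file.path(out_dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$pair_truth,
                     file.path(out_dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(fasta = paths$fasta,
              repeat_library = paths$repeat_library,
              organellar_hits = paths$organellar_hits,
              sam = list(ref1 = paths$sam),
              n_clones = spec$n_clones,
              insert_sizes_kb = lib$clones$insert_len / 1000,
              genome_mb = spec$genome_length / 1e6,
              max_mismatch_frac = if (spec$mutation_rate > 0) 0.05 else 0)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  write_survey_spec(spec, file.path(out_dir, "spec.json"))
  list(config = cfg_path, genome = gen, library = lib, reference = ref,
       paths = paths)
}
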