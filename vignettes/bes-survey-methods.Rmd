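---
title: "Methods: BAC-end sequence genome surveys with bessurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAC-end sequence genome surveys with bessurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bessurvey)
```

## The problem

Before a genome is sequenced, a large-insert BAC library plus a few
thousand Sanger reads off the insert ends (BAC-end sequences, BES) is a
cheap survey of genome structure: GC content, repeat load, microsatellite
density, gene density, and — because the two reads of a clone flank a
~100 kb insert — microsynteny against already-sequenced relatives.
`bessurvey` implements that survey as a set of small, separately testable
stages plus a synthetic-data generator that produces a toy genome,
library and read set with complete truth labels, so that every stage can
be verified exactly at desk scale.

## Models and statistics

**Coverage.** A library of $n$ clones with mean insert $\bar\ell$ (Mb)
over a haploid genome of $g$ Mb represents $c = n\bar\ell/g$ genome
equivalents. Under Poisson sampling the probability that a single-copy
locus is present is $1 - e^{-c}$. `library_stats()` uses the
organellar-excluded clone count when screen results are supplied, since
organellar clones carry no nuclear DNA. Note that $1-e^{-5.73}$ is
99.675%; survey reports that round coverage to ~6x before applying the
formula print "greater than 99.7%", and both renderings are available
from the returned object.

**GC content.** $\mathrm{GC\%} = 100\,(G+C)/(A+C+G+T)$, pooled over
reads. Ns and ambiguity codes are excluded from numerator and
denominator — with Sanger reads containing ambiguous calls this is the
only definition that still estimates genome composition; whether
historical surveys excluded Ns is usually undocumented, so treat
half-percent differences against published values as within convention
noise. Aggregates always pool counts; they are never means of per-read
percentages.

**Microsatellites.** `find_ssrs()` reports maximal perfect tandem
repeats with primitive unit length 1–6 nt: mononucleotide runs of at
least 10 nt, dinucleotides of at least 5 units, tri- to hexanucleotides
of at least 3 units. Motifs are canonicalized over the orbit of cyclic
rotations and the reverse complement (`canonical_motif()`); the
representative is the lexicographic minimum, which fixes only the label —
the grouping itself is the standard one (AG = {AG, GA, TC, CT}, AAG =
{GAA, AAG, AGA, CTT, TTC, TCT}). Numerical choices: runs are broken by
N; trailing partial units are not counted (`total_len = unit_len *
n_units` always); where runs of different unit lengths coincide the
smallest primitive unit wins; among distinct overlapping candidates the
leftmost, then longest, wins, so every nucleotide belongs to at most one
locus. Only perfect repeats are detected — mismatch-tolerant
microsatellite callers will report more loci, so densities are
comparable across tools only qualitatively. Density is
$10^5 \cdot \mathrm{loci}/\mathrm{nt}$.

**Repeats.** Annotations arrive either as RepeatMasker `.out` files
(1-based inclusive query coordinates, converted to 0-based half-open on
read) or as a generic TSV. Class labels map onto a fixed ten-row
taxonomy (Copia, Gypsy, unclassified LTR, LINE/SINE, DNA transposons,
unclassified, small RNA, satellite, simple repeat, low complexity) via an
ordered, user-extensible regex table; unmappable strings become
`Unclassified` with a warning rather than an error. Density is the
percentage of examined nucleotides covered by at least one feature:
per read, intervals are merged per class and overall, so overlapping
annotations never double-count a nucleotide. Per-class numbers use
per-class unions; with non-overlapping classes they sum exactly to the
overall union. `naive_repeat_search()` is a deliberately simple
substitute for an external masker (exact k-mer seeding on both strands,
ungapped extension under a mismatch-fraction budget) used for
self-contained round trips; it is not a production annotator.

**Gene content.** A read is called coding iff it has a BLASTX hit with
e-value strictly below the annotation cutoff (default `1e-6`; the
similarity search itself conventionally uses `1e-5`, and both are
exposed). Top hits break e-value ties by bit score, then file order, so
results are deterministic. Genome-wide extrapolation multiplies the
coding fraction by the genome size and *truncates* to an integer Mb —
a presentation-level choice that reproduces published-style headline
figures exactly from their printed inputs — then divides by an assumed
mean gene length (default 3.4 kb) and rounds to the nearest thousand
genes. GO accounting counts unique (sequence, term) pairs; category
labels are taken from the input table (no ontology traversal), and
per-term percentages are relative to the sequences annotated in that
term's category.

**Microsynteny.** Each clone's two primary end alignments are classified
with rules applied in order: neither end mapped → `unmapped`; one →
`SE`; different reference sequences → `PE_non_colocalized`; same
reference but outer span outside the inclusive 15–350 kb window →
`PE_gapped`; within the window with correct orientation →
`PE_collinear`; otherwise `PE_rearranged`. Design choices, each of which
was genuinely open: the span is the outermost-coordinate difference (the
implied insert span), not the distance between alignment start points;
window bounds are inclusive; "correct orientation" defaults to the
standard paired-end FR geometry (opposite strands, forward-stranded end
on the left), with a strand-opposition-only mode for aligners or
libraries where read direction conventions differ; records below
`min_mapq` (default 20 — no published threshold exists, so the common
BWA convention is used) are treated as unmapped; secondary and
supplementary records are ignored, keeping the module aligner-agnostic.
Categories are always per reference genome — the same clone can be
collinear against one genome and gapped against another.

## The synthetic world

`survey_spec()` defaults state one coherent survey: 41.9% GC; repeat
families totalling ~19.6% of nucleotides with Copia:Gypsy ≈ 1:1.3 and
Class I ≫ Class II; 10.8 SSR loci per 100 kb with class mix
15.7/17.7/12.5/29.8/15.9/8.4% (mono→hexa); inserts truncated-normal with
mean 108 kb on [50, 196] kb; reads truncated-normal with mean 587 nt on
[100, 1255]; 15.3% of clones single-ended (55.9% of those forward);
0.175% organellar reads (chloroplast:mitochondrial ≈ 15:2); 5.4% exact
duplicate reads. Values not stated by any survey were chosen once:
insert SD 16 kb (reproduces ~87% of inserts above 90 kb), read SD
190 nt, consensus lengths 5.0/5.5/3.0/2.5 kb for the four default
families, organellar genomes of 20 and 30 kb at 37/45% GC. Desk-scale
defaults use a 1 Mb genome and 200 clones; all sizes scale.

The generator plants features into i.i.d. background with non-overlapping
rejection sampling (10 nt margin), then *sanitizes*: it repeatedly runs
the SSR miner on the genome and deterministically breaks (i) spurious
background tandem repeats, (ii) flank interference that would extend or
merge a planted locus, and (iii) partial-unit extensions just past a
locus, which are invisible to the floor-truncating miner on the forward
strand but shift the detection phase on reverse-complemented reads.
Repeat consensi and organellar genomes are SSR-stripped before use.
The result is that, with mutation rate 0, the miner, the naive masker
and the pair classifier recover the planted truth *exactly* — which is
what makes green round-trip tests meaningful.

What the generator does **not** emulate: Sanger error profiles, quality
scores, vector/adaptor sequence, chimeric clones, nested or fragmented
repeat copies, compound SSRs, GC heterogeneity along the genome, and
redundancy mechanisms other than exact duplication (survey reports of
redundancy rarely state a definition, so the generator plants exact
duplicate reads and `redundancy()` measures the exact-duplicate
fraction). A green synthetic test therefore establishes correctness of
the accounting and classification logic, not robustness to real
sequencing artefacts.

Randomness: one global integer seed feeds a named stream per sub-step
(background, consensi, placement, inserts, read lengths, ...), so adding
a step never perturbs earlier draws, and identical (spec, seed) produces
byte-identical outputs.

The rearranged reference applies inversions, translocations, insertions
and deletions with non-overlapping source footprints. A read maps iff
its source interval lies wholly inside one contiguously mapped piece;
translocated segments become separate reference sequences (the simplest
deterministic realization of non-co-localized pairs, standing in for
inter-chromosomal moves). Expected categories are recomputed from the
transformed coordinates with the classifier's own rules, then verified
independently through a SAM round trip.

## Degenerate inputs and edge policies

Empty FASTA → empty set with zero totals. Reads shorter than the
100 nt floor are excluded and counted. Duplicate read names are an
error; unparseable end suffixes are kept as `end = unknown` with a
warning. `redundancy()` and `gc_content()` on empty input are errors
(undefined), as are zero-length mapped intervals in the classifier.
`insert_sd = 0` collapses to the mean; zero loci yield density 0 and an
absent spacing. Features out of read bounds are clipped with a warning.
Capacity: requested planted content above 60% of the genome (or any
placement failing 200 rejection draws) is an explicit error.

## Limitations

The naive masker's extension is ungapped, so indel-diverged repeat
copies fragment into several hits; per-class masked totals can overlap
across classes on real annotations (per-class unions are reported, and
the overall union is never double-counted); the microsynteny module
classifies but does not align — alignment quality is whatever the
upstream aligner produced; and published per-class SSR or repeat counts
from other tools are reproducible only distributionally, since their
exact search modes are unstated.
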