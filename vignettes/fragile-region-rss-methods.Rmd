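---
title: "Detecting cryptic recombination signal sequences at chromosomal fragile regions"
author: "fragilerss authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic recombination signal sequences at chromosomal fragile regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragilerss)
```

## Background

V(D)J recombination is initiated when the RAG1/RAG2 endonuclease complex
recognises a recombination signal sequence (RSS): a conserved heptamer
(consensus `CACAGTG`) and nonamer (consensus `ACAAAAACC`) separated by a
nonconserved spacer of 12 or 23 nt. RAGs nick the DNA immediately 5' of the
heptamer. Sequences that resemble an RSS with a few mismatches — *cryptic*
RSS — occur throughout the genome and can be bound and cleaved by RAGs at
reduced efficiency. When RAGs are expressed outside lymphocytes, cryptic RSS
near recurrent structural-variant breakpoints are candidate drivers of
oncogenic rearrangements, a hypothesis raised for glioblastoma, where
cohort breakpoints cluster into narrow "fragile regions".

`fragilerss` implements the in-silico side of that investigation as a
reusable, tested pipeline:

1. **`seqcore`** — sequence primitives, FASTA I/O, and the study's
   oligonucleotide substrates as shipped fixtures.
2. **`rss_scanner`** — detection and scoring of cryptic/canonical 12/23-RSS
   and nick-site prediction.
3. **`breakpoint_cluster`** — grouping cohort breakpoints into fragile
   regions with the 100 bp adjacent-gap rule, plus RSS annotation.
4. **`junction_mapper`** — mapping sequenced recombinant junctions back onto
   their parents: breakpoint intervals, microhomology, inserted bases.
5. **`recomb_stats`** — recombination frequencies from colony counts, fold
   changes, and replicate comparisons.
6. **`expression_strat`** — two-gene percentile stratification of a cohort
   expression matrix into nine subgroups.
7. **`synthetic_data`** — seeded generators producing inputs with the
   statistical structure each stage assumes, standing in for database
   downloads.

## Coordinates and sequence conventions

All internal coordinates are 0-based, half-open. This makes the heptamer
start offset numerically equal to the "nt away from the 5' end" phrasing
used in substrate design (the count of bases preceding the feature): the
canonical substrate AKN1 carries its heptamer 17 nt from the 5' end and
`scan_rss` reports `hept_start0 = 17`.

Input is restricted to the alphabet `A/C/G/T/N`; lowercase is uppercased,
and IUPAC ambiguity codes other than `N` are rejected rather than expanded,
because every substrate this pipeline handles is unambiguous. Genomic
positions printed 1-based inclusive (the COSMIC/browser convention) are
converted on input; BEDPE is consumed 0-based half-open per its standard.

Duplex substrates are stored as annealed strand pairs. Overhangs are
*computed*, never asserted: the maximal exact reverse-complement overlap
between the strands is located, and whatever lies outside it on either end
of either strand is recorded as a 5' or 3' overhang. The type carries 3'
overhang fields as well as 5' ones because one shipped control (MS20/MS21)
leaves unpaired tails at both ends of its top strand.

## The scanner

`scan_rss` enumerates every (heptamer position, spacer, strand) arrangement
and keeps those satisfying the scan parameters:

* `max_heptamer_mismatch` (default 3) and `max_nonamer_mismatch` (default
  4): the loosest mismatch counts described for the study's five fragile
  regions. Both are configurable, and the per-region mismatch counts are
  never hard-coded as truth — reported counts depend on the anchoring and
  spacer conventions of whoever measured them.
* `anchor_cac` (default `TRUE`): the first three heptamer bases must match
  exactly. The CAC core is functionally required for RAG recognition, and
  junction analyses highlight CAC/GTG motifs; a flag allows unanchored
  scanning for sensitivity analyses.
* `spacer_tolerance` (default 0): admit spacers within ± this many nt of 12
  or 23. The CAMK2D substrate illustrates why the knob exists: its best
  cryptic arrangement pairs a 2-mismatch heptamer with a 1-mismatch nonamer
  across a 14-nt spacer, invisible at tolerance 0.

All qualifying hits are reported, including overlapping arrangements — the
AMY1B region, for instance, qualifies as both a cryptic 12RSS and a cryptic
23RSS from the same heptamer — and downstream consumers filter by score.
Bottom-strand hits are found by scanning the reverse complement; each row
carries its own-strand offsets (on which `nona_start0 = hept_start0 + 7 +
spacer` always holds) plus the top-strand start of the heptamer footprint
for genomic bookkeeping. Output order is fully deterministic:
`mismatch_score`, then top-strand heptamer start, then strand (top before
bottom).

Two scores are attached. `mismatch_score` is a transparent ranking
heuristic, `w_h·m_h + w_n·m_n + w_s·|spacer deviation|` with default
weights (2, 1, 1) — heptamer integrity matters most to RAG activity, so it
is weighted double. `model_score` is a pluggable position-frequency
log-odds model: the sum over the 16 heptamer + nonamer positions of
`log(freq/background)` minus a per-nt spacer-deviation penalty. The default
model places frequency 0.91 on the consensus base at the three CAC
positions and the first nonamer position (the A most conserved in nonamer
alignments), 0.70 elsewhere, remainder uniform, uniform background,
pseudocount 1e-3, spacer penalty 1/nt. **These defaults are artifact
choices**, documented as such: they make the exact consensus the unique
maximum and degrade smoothly with mismatches, which is all the pipeline
needs for ranking. Reproducing any externally trained recombination
information content model is explicitly out of scope, but
`rss_model()`/`read_rss_model()` accept such parameters if the user has
them.

`nick_site` returns the heptamer start: the biology (nick 5' of the
heptamer) makes the 5' labelled-fragment length of a top-strand hit equal
to that offset. On substrate oligos designed with the heptamer "21 nt away
from the 5' end", our brute-force placement of the best CAC-anchored
heptamers lands after 20 nt; the one-base discrepancy is a counting
convention we cannot resolve from prose, so the package reports unambiguous
0-based offsets and leaves the translation to phrasing to the caller.

## Breakpoint clustering

The fragile-region rule — "distance between two breakpoints ≤ 100 bp" — is
read as an adjacent-pair gap rule and implemented as single-linkage
chaining per chromosome over sorted positions: a new cluster starts when
the gap to the previous breakpoint exceeds `max_gap`. For intervals as
narrow as the five study regions (spans 47–59 nt) gap-chaining and
maximum-diameter clustering coincide; a `mode = "diameter"` variant that
also caps the maximum pairwise distance is provided for sensitivity
analysis. How many breakpoints qualify a cluster for selection is not
stated anywhere we can cite, so `min_breakpoints` defaults to 2 (a
"cluster" needs a pair) and is configurable. Inter-chromosomal records
contribute one breakpoint per side, clustered independently on their own
chromosomes.

`annotate_cluster_rss` scans a covering window and reports, per hit, the
minimum unsigned distance from any member breakpoint to the nearest base of
the hit's heptamer footprint, sorting by that distance then score — the
quantity behind statements like "most breakpoints were adjacent to a
cryptic RSS".

## Junction mapping

`map_junction` assumes the junction is anchored (first base aligns to the
left parent's start, last base to the right parent's end, e.g. trimmed to
sequencing primers) and computes the longest common prefix `p` against the
left parent and suffix `q` against the right. Overlap is microhomology,
`mu = max(0, p + q − |J|)`; shortfall is untemplated insertion; otherwise
the join is blunt. Exactly one of the three outcomes holds. Microhomology
makes the transition point ambiguous, so the breakpoint is reported as an
interval of length `mu` on each parent; for histograms a canonical
*leftmost* point breakpoint is also emitted — a convention, not a claim
about which repair event occurred. The package deliberately does not call
the repair pathway (MMEJ vs NHEJ); it reports `mu` and inserts and leaves
interpretation to the analyst.

Matching is exact by default. An optional mode skips isolated single-base
mismatches flanked by ≥ 5 exact matches on both sides, accommodating the
point mutations observed in sequenced recombinants; it is off by default so
results are a deterministic function of the inputs. Inverted-orientation
rearrangements are handled by the caller supplying reverse-complemented
parents.

`breakpoint_offset_from_heptamer` gives the signed distance from a scanned
heptamer to the transition (0 = transition at the heptamer's 5' edge, the
canonical RAG geometry; negative = 5' of it), and `junction_histogram`
tabulates offsets over clone sets.

## Frequency statistics

The episomal assay's readout is `f = CA/A × 100` percent (CA: chloramphenicol
+ ampicillin resistant colonies; A: ampicillin-resistant total). Because CA
counts are routinely tiny (0–5), intervals are exact binomial
(Clopper–Pearson, via `stats::binom.test`), valid at zero counts, rather
than Wald. Frequencies are carried in percent end-to-end — the unit the
assay reports — with conversion only at I/O boundaries. `fold_change`
handles the observed zero-recombinant case by returning `Inf` with a flag
instead of failing. Replicate comparisons use the classic pooled-variance
Student's t test (matching the stated analysis; Welch via a flag), with the
reporting convention `*` p < 0.05, `**` p < 0.005, `***` p < 0.0001, `ns`
otherwise, and the degenerate equal-constant case resolved to p = 1.

## Expression stratification

Cohort expression (FPKM/RPKM) is analysed as `log2(x + 1)`; the two names
appear interchangeably in source material, and since the stratification
depends only on ranks, any strictly increasing rescaling yields identical
labels (a property the tests assert). Per gene, samples are classed against
that gene's own 25th/75th percentiles: Low strictly below q25, High
strictly above q75, Medium otherwise — boundary ties go to Medium because
the defining inequalities for Low and High are strict. Quantiles use linear
interpolation between order statistics (R type 7), a choice the source
does not state and we therefore document rather than defend. The two
per-gene classes combine into nine labels (`R1L/R2L` … `R1H/R2H`);
`group_counts` always reports all nine, with zeros.

## What the generators emulate — and what they do not

Every generator is a pure function of its parameters and an explicit
integer seed (`withr::with_seed`; no global RNG state is touched), and
identical calls are byte-identical.

* `gen_rss_sequence` plants a heptamer/nonamer pair with *exactly* the
  requested mismatch counts (CAC preserved when anchoring is requested) in
  i.i.d. background of stated GC content — mirroring substrate design,
  where a cryptic signal sits at a fixed offset in an otherwise arbitrary
  oligo. An optional first-order Markov background exists because motif
  false-positive rates depend on dinucleotide structure; default off.
* `gen_breakpoint_records` plants clusters whose realised span equals the
  requested span (first and last member pinned), separated by gaps chosen
  large enough that the 100 bp rule provably recovers the planted
  memberships. Defaults in examples mirror the printed geometry (e.g. a
  2-breakpoint cluster spanning 59 nt, the CAMK2D interval width).
* `gen_junction_reads` builds junctions from explicit cut sites, verifying
  that a requested microhomology is actually supported by a shared word at
  the cuts, and records as truth the `(p, q, mu, insert)` values the mapper
  recovers at zero error — so flanking homology in the parents is part of
  the truth, not a surprise.
* `gen_colony_counts` draws `CA ~ Binomial(A, p)`; the calibration tests
  run it at the assay's scale (A = 10^6, p = 3.2×10^-5, i.e. 0.0032%).
* `gen_expression_matrix` draws each sample's class from stated
  proportions, then its log2 expression from a three-component normal
  mixture (component means `centre ± separation`, sd 0.3, centre 4 — a
  plausible mid-range log2 FPKM), returning `2^x − 1` so the standard
  transform recovers the simulated scale exactly. Default proportions
  (0.25, 0.5, 0.25) place the percentile thresholds between components.

What passing tests on these inputs shows is that the *operations* meet
their contracts: the scanner equals exhaustive enumeration, clustering
recovers planted structure, the mapper inverts the junction construction,
the estimator is calibrated. What they do not show is performance on real
data: real breakpoint sheets have batch structure and ambiguous records,
real junction reads have indels and chimeras beyond isolated substitutions,
real expression matrices have correlated genes and heavier tails, and real
genomic background is not i.i.d. The generators are sufficient for
correctness testing, not for benchmarking sensitivity/specificity claims.

## Numerical and degenerate-input choices

* Scanner ties: sorted by score, then top-strand position, then strand —
  no nondeterminism anywhere in the pipeline's default path.
* Sequences shorter than the minimal RSS footprint scan to an empty table,
  not an error; an empty breakpoint file clusters to an empty table.
* `A = 0` colonies is an error (frequency undefined); `CA > A` warns but
  proceeds, since miscounted plates occur and the caller may still want the
  row.
* Model scoring guards zero-probability bases with a pseudocount, required
  to be positive at construction.
* Junction mapping with no anchored prefix or suffix on either side is an
  error ("junction unrelated to parents") rather than a zero-length call.

## Problem sizes

The shipped test-suite and acceptance checks use: 100 random 200-nt
sequences for scanner/oracle equivalence; junctions up to 30 nt against
exhaustive transition enumeration; 1,000 binomial replicates at A = 10^6
for estimator calibration; cohorts of 120–400 samples for stratification.
These sizes give the properties room to fail while keeping the full suite
comfortably fast on a laptop.

## Known limitations

* The scanner models heptamer + spacer + nonamer arrangements only — no
  paired 12/23 synapsis, no hairpin/transesterification chemistry, no
  non-B DNA structure detection (G4, cruciform), although such structures
  are also RAG substrates.
* The default scoring model is a ranking device, not a trained model of
  recombination efficiency; do not interpret its absolute values.
* The junction mapper requires anchored junctions and handles substitution
  noise only in its optional tolerant mode; indel sequencing errors shift
  `p`/`q` rather than being corrected.
* Stratification thresholds are cohort-internal percentiles; labels are not
  comparable across cohorts processed separately.
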