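---
title: "Methods: homology- and structure-based miRNA discovery without a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology- and structure-based miRNA discovery without a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirforge)
```

## The problem

Plant species without an assembled reference genome — tea
(*Camellia sinensis*) being a prominent example — cannot use standard
genome-anchored miRNA callers. `mirforge` implements the workflow such
studies use instead: small RNA sequencing reads are cleaned, collapsed to
unique tags and filtered; conserved miRNAs are recognized by
mismatch-tolerant homology to mature miRNAs of other species; candidate
novel miRNAs are validated structurally by folding genome-survey
scaffold windows around each tag locus and applying a battery of twelve
stem-loop criteria; and the calls are followed downstream by target
prediction, cleavage-site mapping, expression mathematics and pathway
enrichment. A genome-survey module estimates the (unassembled) genome
size from the k-mer spectrum of whole-genome shotgun reads.

Everything is testable offline: the `synthetic_data` functions plant
hairpins with known mature sequences into random scaffolds and simulate
every input the pipeline consumes, so each stage can be checked against
a complete truth table.

## Read preprocessing

`clean_reads()` trims the 3' adapter at the leftmost exact match of at
least 8 adapter bases, then removes reads shorter than 15 nt (the
conventional minimum for a usable insert), reads with ambiguous bases
beyond `max_n`, and — when qualities are available — reads with mean
Phred below 20. "Low quality" is rarely given a precise definition in
study write-ups; the mean-Phred rule is our operationalization, and
FASTA input simply skips it. A Shannon-entropy dust filter
(< 1 bit/nt would be a typical threshold) is available but off by
default, since low-complexity removal criteria differ between vendor
pipelines.

`collapse_reads()` produces unique tags with counts (`tag{n}_x{count}`
naming), `length_distribution()` tabulates the read-weighted and
unique-tag size spectrum *before* size selection — the full 15–30 nt
picture is part of standard library QC — and `size_select()` then keeps
the 17–25 nt window used for miRNA discovery. `filter_ncrna()` removes
tags occurring as substrings of rRNA/tRNA/snoRNA/snRNA references on
either strand; matching is exact by default (a mismatch allowance is
exposed) and includes the reverse complement because strandedness of
contaminant databases is unreliable.

## Genome survey by k-mer spectrum

`count_kmers()` counts every N-free window of length *k* (default 17)
on the given strand. `find_peak()` returns the depth with the most
distinct k-mers, ignoring depths below 4 to avoid the sequencing-error
peak, with ties broken toward the smaller depth. Genome size is then

> genome size = total k-mer count / peak depth,

computed exactly and also reported truncated (not rounded) to two
decimals in Gb, which is how such survey numbers are conventionally
printed. Canonical (strand-merged) counting is available behind a flag
but off by default, matching the strand-naive statement of the formula.
`coverage()` is the plain ratio of sequenced bases to genome size; no
attempt is made to model heterozygosity or repeat structure of the
spectrum.

## Conserved miRNA identification

`match_known()` compares each tag to a reference of known mature
miRNAs after normalizing both sides to the DNA alphabet (so U and T
never count as a difference). Matching is whole-tag, ungapped, with at
most 3 substitutions and terminal shifts of up to 2 nt; the overlap
must cover at least `tag length − 2` positions. The shift tolerance
absorbs isomiR-style end variation. A tag hitting several references is
assigned once, to the best hit (fewest mismatches, smallest shift, then
lexicographically smallest name), which keeps `family_census()`
memberships disjoint. Families are parsed from miRBase-style names
(`ath-miR166a-5p` → `miR166`).

## Hairpin evaluation

For each tag locus on the scaffolds (`locate_tag()`, exact matching on
both strands), `extract_windows()` emits two candidate windows placing
the tag toward either precursor end (`[start − flank, end + 20]` and
`[start − 20, end + flank]`, flank 200 nt, clipped to 300 nt), reverse
complemented on the minus strand so the tag reads 5'→3'.

Windows are folded by `fold_rna()`. The default backend is ViennaRNA's
`RNAfold` when the executable is on the `PATH`; a built-in weighted
base-pair-maximization dynamic program (G:C 3, A:U 2, G:U 1, minimum
loop 3 nt) provides a self-contained alternative behind the same
interface. Both are deterministic. The structural criteria are designed
to be robust to the backend choice: synthetic stems are made
thermodynamically dominant (≥ 85% Watson–Crick pairs), so any
reasonable folder recovers them.

A folded 300-nt window almost always carries incidental base pairs in
its random flanks, so the raw window is rarely a clean stem-loop.
`mature_stem_component()` therefore extracts the maximal unbranched
stem-loop whose stem involves the mature tag — walking outward from a
mature base pair while enclosing pairs are directly nested, and inward
to the terminal loop; tags sitting above a multi-branched loop are
rejected. The trimmed candidate is re-folded and becomes the reported
precursor, which also guarantees that every stored call re-validates
(re-folding the stored precursor reproduces the stored structure and
energy).

`compute_metrics()` derives, from the pair table: length, GC%,
AMFE = (|MFE| / length) × 100, MFEI = AMFE / GC% (the positive-magnitude
convention, so typical values fall in 0.4–2.8), stem pairs, the largest
stem bulge, terminal loop length, and mature-region tallies (paired
positions, unpaired nucleotides, largest bulge on the mature side,
one-sided "biased" bulges, and the fraction of the mature region inside
the stem).

`apply_criteria()` evaluates the twelve screening rules with these
defaults (all configurable through `criteria_config()`):

| # | rule | threshold |
|---|------|-----------|
| 1 | largest stem bulge | ≤ 12 nt |
| 2 | stem base pairs | ≥ 16 |
| 3 | hairpin length | ≥ 50 nt |
| 4 | terminal loop | ≤ 200 nt |
| 5 | one bulge in mature region | ≤ 4 nt |
| 6 | one biased (one-sided) mature bulge | ≤ 2 nt |
| 7 | biased bulges in mature region | ≤ 2 |
| 8 | unpaired nt in mature region | ≤ 4 |
| 9 | base pairs in mature region | ≥ 12 |
| 10 | mature region within the stem | ≥ 80% |
| 11 | folding free energy | ≤ −12 kcal/mol |
| 12 | MFEI | ≥ 0.7 (≥ 0.4 with a predicted target) |

Rule 1 is sometimes printed in the literature with the inequality
reversed ("≥ 12 nt in one bulge"), which would *require* a large defect
and contradicts every other rule; we implement the standard reading (a
cap on bulge size) and keep the threshold configurable. An MFEI of
≥ 0.85 is additionally reported as a high-confidence flag — it does not
gate the verdict. Multi-branched candidates fail a single-stem gate
before the criteria are applied. Among passing windows of a locus the
lowest-MFE candidate wins, ties broken by shorter precursor.

`classify_tag()` then assigns the discovery groups: **1** — known
homolog with a criteria-passing local hairpin; **2a** — known homolog
with a genomic locus but no passing hairpin; **2b** — known homolog
with no genomic locus at all (supported only by the foreign precursor);
**3** — no homolog but a passing hairpin (novel, numbered
`csn-miRn{k}` in order of decreasing read support). Tags with neither
evidence are discarded. The exact boundary between 2a and 2b is our
stated convention (2a = locus present, hairpin imperfect; 2b = no
locus); published screening schemes describe these groups only
diagrammatically.

## Target prediction and cleavage mapping

`score_duplex()` implements plant-style complementarity scoring of an
antiparallel miRNA:site duplex: ordinary mismatch 1.0, G:U wobble 0.5,
each bulged nucleotide 1.0, all penalties doubled at miRNA positions
2–13; at most one single-nucleotide bulge (site length within ±1 of the
miRNA). The reported alignment is the exact minimum over all bulge
placements — the search space is small enough to enumerate, and the
test suite checks it against an independent recursive enumeration.
`scan_transcriptome()` reports every window scoring at or below the
cutoff (default 4.0), deduplicating overlapping windows to the local
minimum. The penalty table and cutoff follow the established
plant-target-finder convention; no probabilistic "expectation" model is
layered on top, since none is specified in that convention.

`map_cleavage()` translates cloned transcript 5' ends (RLM-RACE style)
into boundaries between miRNA positions: a 5' end at transcript
position *p* inside the site abuts the boundary between miRNA positions
`site_end − p + 1` and the next. Plant slicing canonically falls
between the bases pairing miRNA positions 10 and 11, which is reported
as a `canonical` flag; counts are conserved between in-site and
out-of-site clones.

## Expression mathematics

`microarray_qc()` applies the spot filters in their conventional order:
background subtraction first, then removal when the corrected signal is
below 3 × background SD or the replicate CV exceeds 0.5, then
`non_expressed` below 30, `low_abundance` below 100 (kept, excluded
from variance analysis), else `expressed`. Whether the 3×BSD rule
should see raw or subtracted signal is ambiguous in most write-ups; we
use the subtracted signal (configurable). CV is computed on
background-subtracted replicates before normalization, because the CV
rule belongs to the pre-analysis spot filters.

`lowess_normalize()` removes intensity-dependent bias with an MA-style
locally weighted regression of each channel's log-ratio against the
per-probe mean log-signal (span 0.3), the standard choice for
single-channel miRNA arrays. Identical channels pass through unchanged
and the operation is idempotent to numerical tolerance.

Two distinct qRT-PCR quantities are implemented with pinned signs so
that more abundant ⇒ larger value in both:
`rel_expression_dct()` returns `2^(Ct_control − Ct_gene)` (abundance
relative to U6), and `fold_change_ddct()` returns `2^(−ΔΔCt)` with the
reference sample mapping to exactly 1. `correlate_pairs()` reports
Pearson and Spearman coefficients with a direction flag; zero-variance
profiles yield an explicit error flag rather than NaN.

## Enrichment

`hypergeom_tail()` is the one-sided over-representation tail
`P(X ≥ k)` for `k` annotated genes among `n` drawn from a universe of
`N` containing `K` annotated; `enrich()` applies it per term with the
enrichment call at raw p ≤ 0.05 and optional Benjamini–Hochberg
q-values (off by default — the workflow this reproduces filtered on raw
p). Genes without annotation stay in the universe; by default the
universe is all genes appearing in the annotation table, configurable
where the caller's transcriptome is wider. `go_classify()` tabulates
term assignments per namespace with percentages summing to 100 within
each namespace.

## The synthetic data generator

`make_genome()` plants `arm + loop + reverse-complement(arm)` hairpins
(default stem 24 nt, loop 8 nt, ~8% of stem positions converted to G:U
wobbles and ~4% to mismatches) at non-overlapping positions in i.i.d.
uniform ACGT scaffolds; at desk scale random background essentially
never produces a competing criteria-passing hairpin, and two trailing
scaffolds are kept hairpin-free as negative controls. Mature lengths
are drawn from {24: 55%, 21: 25%, 22: 10%, 23: 10%}, emulating the
24-nt-dominant, 21-nt-secondary size profile typical of plant small RNA
libraries. `make_reads()` samples reads from the mature arms with
0–2 nt end jitter, mixes in contaminant reads drawn from an ncRNA
reference, and applies i.i.d. substitution errors. DNA alphabet is used
on disk (T, not U), matching FASTA/FASTQ convention.

What the generator does *not* emulate: RNA degradation, isomiR biology
beyond end jitter, adapter read-through beyond a single configurable 3'
adapter, repeat-rich genomic background, and multi-locus miRNA
families. Passing tests on synthetic data therefore demonstrate the
correctness of the algorithms under the stated model, not performance
on real libraries with those complications.

## Problem sizes and numerical choices

The validation bundle used by the test suite and the acceptance script
is 20 scaffolds × 50 kb (1 Mb total) with 20 planted hairpins, 10 of
them emitted into the synthetic known reference (divergence ≤ 2), read
depth 50 per locus and no sequencing errors; discovery considers tags
with count ≥ 2. These sizes exercise every stage — including both
conserved and novel recovery and the background-scaffold negative
control — at desk scale. Determinism is enforced throughout: every
stochastic generator takes a seed and restores the caller's RNG state;
both folding backends are deterministic; ties are broken by explicit
rules (smaller depth for k-mer peaks, lexicographic names for equal
homology hits, shorter precursor for equal MFE).

Degenerate inputs are handled explicitly: GC = 0 makes MFEI undefined
and fails criterion 12; an all-unpaired structure yields MFE 0 and
AMFE 0; zero-variance expression profiles set an error flag; empty tag
sets, empty annotations and empty hit lists return empty, well-typed
results.

## Known limitations

* Coverage estimates from survey data are the plain base ratio;
  published coverage figures derived from undisclosed read filtering
  cannot be reproduced from the printed totals alone.
* Group 2a/2b semantics follow our stated convention, not a verbatim
  published definition.
* The duplex scanner is O(transcript × miRNA) per window with at most
  one bulge; larger internal loops are rejected rather than scored.
* Absolute counts from real studies (numbers of conserved/novel miRNAs,
  targets) depend on raw data and proprietary reference versions and
  are out of scope; the package validates the *procedures* on synthetic
  truth instead.
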