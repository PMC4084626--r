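---
title: "Read-split-walk: rescuing unmapped reads to find short non-canonical splices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-split-walk: rescuing unmapped reads to find short non-canonical splices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsw)
```

## The problem

Standard RNA-Seq alignment maps reads against a genome expanded with a
library of known exon-exon junctions. Any read that truly spans an
*unannotated* excision — the canonical example being the 26 nt interval
that IRE1α removes from *Xbp1* mRNA in the cytosol during ER stress — has a
gap in it that neither reference can absorb, so it lands in the unmapped
pile. Short excisions of this kind are invisible to spliced aligners tuned
for spliceosomal introns and too small to resolve from paired-end insert
sizes; but they are recoverable from the unmapped single-end reads
themselves, which is what this package does.

## The procedure and its assumptions

Given the unmapped read set, a genome, and gene models, `rsw_detect()`
performs:

1. **First-pass emulation** (optional, `phase1 = TRUE`). On synthetic data
   the package itself decides which reads are unmapped: a read is mapped
   when it, or its reverse complement, occurs full-length and exactly in
   the genome or in the exon-junction library (flanks of
   `read_length − 4` nt per side, so a read must overhang a known junction
   by ≥ 4 nt to be absorbed by the library). On real data you would pass
   the aligner's leftover FASTQ and set `phase1 = FALSE`. The emulation is
   exact-match only: it is intended for the error-free simulated reads the
   generator produces, where it is equivalent to a mismatch-tolerant first
   pass; reads carrying sequencing errors simply join the unmapped set and
   are weeded out later by the zero-mismatch half placement.
2. **Trim** the 3′-terminal `trim_bases` (2) bases — the lowest-quality
   cycles on the targeted platforms.
3. **Split** each read at every offset in
   `min_half .. L − min_half`, giving `L − 2·min_half + 1` left/right
   pairs per read.
4. **Place** every half on both strands of the genome with zero
   mismatches. Zero tolerance is deliberate: an 11 nt half placed with one
   mismatch matches vast numbers of loci, and mismatch-tolerant placement
   floods the promiscuity filter (`max_locations`, 10) to the point of
   destroying true signal. `N` never matches.
5. **Pair** left and right placements of the same split: same chromosome,
   same strand, at least one shared gene (gene extent is the union span of
   its transcripts — the most permissive defensible reading of "same
   gene"), not inverted (on `+`, the left half must lie upstream; on `-`,
   downstream), nearest-end gap ≤ `max_distance` (40 kb, an intron-scale
   bound; 50 kb is a reasonable human setting), and gap length ≥ `min_gap`
   (2 — 0–1 bp gaps arise from split-point homology, not splicing).
6. **Consolidate** pairs with identical splice length whose gap starts
   agree within `slip_threshold`, by single-linkage clustering on the gap
   start (with equal lengths, start and end differences are identical;
   single linkage reproduces the min-start .. max-end merged extent).
   Sequence homology at the excision edges shifts the placed boundary of a
   junction-spanning read by a few bases, which is why slippage must be
   tolerated and why a candidate's merged region can slightly exceed the
   true excised interval.
7. **Filter**: a candidate is *known* (not novel) when any supporting gap
   has both boundaries within `junction_proximity` (5) bp of an annotated
   intron's corresponding boundaries; candidates with fewer than
   `min_support` (2) distinct supporting reads are dropped. Support counts
   distinct read ids — no duplicate collapsing — and a read validly pairing
   into two clusters supports both (flagged `ambiguous_reads`).
8. **Rank** by descending support, ties by ascending splice length then
   position. Support, not a significance model, is the ranking statistic:
   with 2-read candidates reported for completeness, the support
   distribution itself is what separates convincing hits from noise.

`rsw_compare()` implements the case/control contrast: any control read
whose gap matches both case-region boundaries within `control_variance`
(5) bp vetoes the candidate — raw control *pairs* are consulted, not just
consolidated control candidates, so a single control read suffices
(conservative), while control matches below the minimum gap never veto.
`rsw_combine()` intersects two runs (two treatments, or the two ends of
paired-end data, each end processed as an independent single-end run):
same gene, same splice length, at least one boundary within
`control_variance`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `trim_bases` | 2 | 3′ bases removed before splitting |
| `min_half` / `max_half` | 11 / `L − min_half` | half-length bounds; 33 nt reads walk 11–22, 77 nt walk 11–66; thirds-based runs (99 nt: 33–66) are obtained with `min_half = 33` |
| `max_mismatches_halves` | 0 | zero-mismatch half placement (see above) |
| `max_locations` / `report_limit` | 10 / 11 | promiscuity cut-off and report cap |
| `max_distance` | 40 000 | maximum gap span (bp) |
| `min_gap` | 2 | minimum splice length (bp) |
| `slip_threshold` | 11 (L=33), 27 (L=77), else `round(L/3)` | consolidation slippage (bp) |
| `junction_proximity` | 5 | known-intron tolerance (bp, per boundary) |
| `min_support` | 2 | distinct reads per candidate |
| `control_variance` | 5 | case/control and run-combination boundary tolerance (bp) |

The two calibrated slip thresholds cover the two read lengths the defaults
target; no closed-form rule behind them is established, so other lengths
fall back to `round(L/3)` — a configuration default, not an assertion, and
always overridable. Intron strand is ignored when matching candidates to
known introns: annotation strand mix-ups should make the novelty filter
*more* conservative, never less.

## The synthetic-data generator

`generate_reference()` builds uniform-random chromosomes with non-
overlapping multi-exon genes on both strands (introns ≥ 50 nt);
`plan_excisions()` implants excisions centred in the widest exon with
≥ 20 nt clearance from exon boundaries, so implants are non-canonical by
construction and beyond the novelty filter's reach — isolating the
detection question from the annotation question. `simulate_reads()` draws
uniform-position single-end reads from mature transcripts; in target genes
a `penetrance` fraction of reads comes from the excised form. Everything
is seeded and byte-reproducible.

Defaults emulate the study design the method was built around: 35 nt
single-end reads at 50× coverage, an Xbp1-like 26 nt excision at
penetrance 0.5 in the case sample, penetrance 0 in the control. Under this
geometry the expected support is roughly
`n_spliced_reads · (L − 2·min_half + 1) / (template_length − L_raw + 1)`
(the fraction of junction-spanning reads leaving ≥ `min_half` on each
side) — about 9 reads for the default 900 nt transcript — plus a
comparable-order contribution from boundary-slipped placements when the
excision edges happen to share sequence.

Reads default to sense-strand orientation (as in a strand-specific
library); with `orientation = "random"` support for one locus splits
across the two strand groups, which is realistic for unstranded libraries
but blurs the single ground-truth cluster the fixtures exist to pin down.
What the generator does *not* emulate: empirical error profiles and
quality models, expression heterogeneity, paired-end fragment geometry,
repeat-rich genome structure (beyond an optional planted tandem array for
exercising the promiscuity path). Passing tests on this generator
demonstrate the selection logic, not robustness to those real-data
features.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally and in TSV
  output; refFlat input (0-based half-open) is converted exactly once at
  load, and BED export converts back on write.
* Junction-library flanks truncate at exon boundaries; library sequences
  are emitted on the genome's + strand with transcript strand carried in
  the record name, matching an aligner's indifference to read orientation.
* Adjacent placements (`splice_length` 0–1) are computed, tabled with
  `pass_min_gap = FALSE`, and excluded from consolidation — keeping them
  available as control-side evidence without letting them found candidates.
* Ties everywhere break deterministically (position order; `+` before `-`;
  first gene symbol in sort order when halves share several genes), so
  identical inputs give identical reports.
* Empty inputs (no reads, no genes, single-exon transcripts) flow through
  and yield empty, well-formed outputs.
* One detection run at the default fixture scale (two 20 kb chromosomes,
  ~7,700 reads) takes tens of seconds; the design target is desk-scale
  validation and method study, not production alignment throughput. For
  real datasets, halves can be exported as FASTA and placed by an external
  zero-mismatch aligner, with the SAM ingested via
  `read_half_alignments()`.

## Known limitations

* The first-pass emulation is exact-match; with real, error-bearing reads
  the unmapped set must come from a real aligner run.
* Half placement pairs genome hits only; junction-library placements enter
  the mapped/overflow bookkeeping but do not form pairs. Whether such hits
  should participate in pairing is genuinely undetermined; pairing genome
  hits only is the conservative choice.
* No significance model is attached to support counts, and no
  trans-chromosomal or unbounded-distance search is attempted by default
  (`max_distance` can be raised at the user's own risk).
* "Independent reads" means distinct read identifiers; PCR duplicates are
  not collapsed.
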