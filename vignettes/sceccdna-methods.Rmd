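---
title: "Methods: single-cell eccDNA detection and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell eccDNA detection and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection model

A circular DNA template excised from interval `[s, e)` of a linear
chromosome produces sequencing fragments on a circularised coordinate
system of length `L = e - s`: fragment start positions are uniform on the
circle and a fragment of length `f` wraps through the junction with
probability `(f - 1) / L`. On the linear reference, a wrapped fragment
leaves one of two signatures:

1. **Split read.** If one read of the pair crosses the junction, its
   alignment is divided: the part before the junction aligns ending at
   `e`, the remainder aligns starting at `s`. In BAM terms this is a
   primary alignment with a soft-clipped tail plus an SA-linked
   supplementary alignment on the same chromosome and strand. The implied
   junction interval is exactly `(s, e)`.
2. **Discordant outward pair.** If the pair straddles the junction without
   either read crossing it, the right-end read maps near `s` on the
   reverse strand and the left-end read maps near `e` on the forward
   strand: an RF ("outward-facing") pair. Its implied interval
   `(leftmost start, rightmost end)` underestimates `(s, e)` by up to a
   fragment length on either side, which is why split evidence anchors
   call boundaries and discordant evidence contributes support.

The caller streams a coordinate-sorted BAM once, skipping duplicate and
secondary records; split evidence requires same chromosome, same strand,
both alignments at or above the mapping-quality floor, and an implied span
at most `max_span_bp`. Evidence is then single-linkage clustered per
chromosome: two records link when *both* their left and right breakpoints
agree within `cluster_tolerance_bp`. The cluster boundary is the modal
breakpoint among split evidence when any exists, otherwise the lower
median of the discordant breakpoints; all ties break toward the smaller
coordinate so that calling is deterministic.

Candidates face two gates. The **support gate** passes a candidate with
`n_split >= min_split`, or `n_split >= min_split_with_disc` together with
`n_discordant >= min_disc`; discordant-only clusters never pass, since the
breakpoint scatter of outward pairs routinely produces spurious
low-support clusters near a real junction. The **evenness QC** cuts the
candidate interval into `evenness_bins` equal bins and requires at least
`evenness_min_frac` of them to be overlapped by at least one mapped read
(any mapped read, not only junction evidence — sparse single-cell data
rarely tiles an interval with junction reads alone). This mirrors the
observation that very long candidates are typically breakpoint artifacts
whose interiors are empty; candidates longer than `max_span_bp` are
likewise emitted with a fail status rather than silently dropped.
Intervals shorter than the bin count degenerate to one bin per base.

### Caller parameters

| parameter | default | meaning |
|---|---|---|
| `min_mapq` | 10 | mapping-quality floor for any contributing alignment |
| `cluster_tolerance_bp` | 10 bp | single-linkage breakpoint tolerance |
| `min_split` | 2 | split support sufficient alone |
| `min_split_with_disc` / `min_disc` | 1 / 2 | combined support gate |
| `max_span_bp` | 1,000,000 bp | maximum candidate span |
| `evenness_bins` | 20 | QC bins |
| `evenness_min_frac` | 0.8 | minimum covered-bin fraction |

These defaults are calibrated for desk-scale synthetic data and are all
exposed, since published eccDNA callers rarely document their exact
settings and real data will need tuning (deeper data can afford higher
support thresholds; noisier mapping needs a larger tolerance).

## Barcode tracing and the count matrix

Each evidence record carries the `CB` cell barcode of its read. The
eccDNA-by-cell matrix sets `counts[i, j]` to the number of evidence
records supporting call `i` with barcode `j`. Records with a missing
barcode, or a barcode absent from the user-supplied cell table, are
excluded and counted in a diagnostic — the cell table defines the
analysis denominator, the package's analogue of a QC-passed cell set. A
cell *harbors* eccDNA iff its column sum is at least 1; harboring
fractions are reported per group as percentages with two decimals. Counts
are evidence reads, not deduplicated fragments; a `dedup` switch (same
barcode, identical breakpoints counted once) is provided and off by
default. Whether published per-sample percentages use all barcodes or
QC-passed cells as denominator is generally unstated; here the choice is
explicit and configurable through the cell table.

## The common catalogue

Per-sample calls are merged by transitive overlap: records overlap when
they share at least one base under 1-based inclusive coordinates (merely
touching intervals do not merge), and a merged region spans the minimum
start to maximum end of its members. "Common eccDNAs shared across
samples" is implemented as this union-merge over the pooled records; a
`min_samples` filter offers the intersection reading. On the packaged
nine-sample GBM catalogue the union reading yields exactly 30 regions,
which is the reading consistent with its published summary.

Coordinate conventions: printed locus strings (`chr2:89823776-89842856`,
any dash dialect, thousands separators tolerated) are 1-based inclusive
and are converted internally to 0-based half-open. The default span
metric is the printed-coordinate difference `end - start`, because that is
the arithmetic behind the catalogue's published 306 bp minimum; the
half-open width (one base larger) is available as `internal` mode. The
catalogue's published *maximum* span (145,754 bp) is not derivable from
any single or merged record in the table (the maximum raw printed span is
98,265 bp); the package reports what it computes and does not force that
figure.

## Annotation

Gene models are read from GTF/GFF; introns are gaps between consecutive
exons in transcription order, and the first exon/intron are strand-aware.
Each region receives the highest-priority category it overlaps by at
least 1 bp (half-open): promoter > first exon > other exon > first intron
> other intron > downstream > distal intergenic. The promoter footprint is
the strand-aware window `[TSS - 2000, TSS + 200)` and the downstream
footprint extends 3,000 bp past the gene end — conventional annotator
defaults, configurable because the tools this mimics do not standardise
them. The category set deliberately includes `other_exon` and
`downstream` even though five-way summaries often omit them; they are
reported as-is when inputs hit them. Candidate cis-regulatory elements
come from a BED whose name column holds the class (`prom`, `enhP`,
`enhD`, `K4m3`, `CTCF`); region-by-class counts use the same >= 1 bp
half-open overlap, so an element abutting a region's end does not count.

## Coverage and group statistics

Linear coverage counts properly paired, non-duplicate, mapq-passing reads
per bin and cell cluster; circular coverage counts outward-pair mates,
plus split primaries when `include_split` is on — whether published
"circular coverage" includes split reads alongside discordant ones is
ambiguous, so both definitions are available. Each read is counted once,
in the bin holding its leftmost base inside the region, so bin sums
conserve read counts and profiles are additive over disjoint cluster
partitions. Per-cell signal for one call is its matrix row, optionally
divided by the cell's total count over all calls; raw counts are the
default since the normalisation behind published per-cell distributions
is typically unstated.

The group tests are implemented in-package because their contract
includes exact enumeration with ties: the rank-sum null is enumerated
over all `choose(n, nx)` labelings of the pooled midranks, and the
signed-rank null over all `2^n` sign patterns, so tied data still get
exact two-sided p-values (`P(|T - mu| >= |t_obs - mu|)`, valid because
both nulls are symmetric under rank reflection / sign flip). The
auto mode switches to the tie-corrected normal approximation with
continuity correction above a combined n of 12 — small enough that the
enumeration stays instant and large enough that the approximation is
already within 0.02 of exact for tie-free samples. Kruskal-Wallis uses
midranks with the standard tie correction and a chi-square reference with
k - 1 degrees of freedom. Degenerate inputs (all observations tied, all
paired differences zero) report p = 1 with a warning rather than erroring.
Star labels use strict inequalities (`****` < 0.0001, `***` < 0.001,
`**` < 0.01, `*` < 0.05, otherwise `ns`); no multiple-testing correction
is applied by default, with a Benjamini-Hochberg helper for
catalogue-wide scans.

## What the simulator emulates — and what it does not

The simulator generates a uniform-random A/C/G/T genome, plants
non-overlapping circles with spans uniform in a configured range, assigns
each circle to each cell independently with a per-cell-type presence
probability (copy number fixed at 1), draws per-cell read-pair counts
from a Poisson, fragment lengths from a truncated normal, and emits
truth-aligned reads directly — primary/supplementary split alignments
with SA tags, outward discordant pairs, properly paired background — so
no aligner is needed; a FASTQ mode exists for users who want to run one.
A junction-crossing read is written as a split alignment only when both
pieces are at least 20 bp (`min_clip`); below that, real aligners could
not anchor the clip either, and the pair is emitted as discordant-only
evidence, which keeps the accounting identity *junction-crossing
fragments = split pairs + discordant pairs* exact. Every operation is a
pure function of its inputs and the seed.

Deliberately not modelled: sequencing errors by default (a substitution
rate is configurable; detection logic is positional), PCR duplicates,
nucleosome-periodic fragment sizes, Tn5 insertion bias, chimeric
inter-chromosomal artifacts, doublets, and barcode errors. Passing tests
on this generator therefore demonstrate the correctness of the evidence
extraction, clustering, QC, tracing and accounting logic under ideal
mapping — not robustness to alignment noise, repeats, or open-chromatin
coverage structure in real scATAC-seq.

## Problem sizes and numerical choices in the test suite

The detection-recovery study uses 5 circles of 1–20 kb on a 500 kb
two-chromosome genome, 2,000 cells, presence probability 0.1, ~50 read
pairs per cell (about 100,000 fragments), and requires recall and
precision of at least 0.95 with boundaries within ±10 bp; with exact
truth alignments the caller recovers boundaries exactly, so the tolerance
headroom covers clustering tie-breaks. The barcode-tracing study uses one
1–1.5 kb circle at deep coverage (~90 pairs/cell, 80% of a positive
cell's fragments from its circle) in 2,000 cells so that a circle-positive
cell yields at least one qualifying split read with probability above
99.9%, making the detected harboring fraction an almost unbiased estimate
of the planted presence probability; the test checks it against the
binomial 99% interval at n = 2,000. Interval merging is verified against
an O(n²) union-find brute force on 100 random instances of up to 200
intervals, and the rank-based tests against base R's implementations on
tie-free data plus hand-enumerated tied cases.

## Known limitations

* Same-chromosome, same-strand junctions only; no inter-chromosomal or
  inverted structural variants.
* Boundary precision is bounded by the simulator's exact truth
  alignments; with a real aligner, indel slippage around junctions will
  widen the breakpoint scatter beyond the 10 bp default tolerance.
* The evenness QC, like the approach it models, discards real
  low-coverage long circles; a split-read-only rescue mode for such
  candidates is noted but not implemented.
* Counts are junction-evidence reads, a lower bound on circle molecules;
  no copy-number inference is attempted.
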