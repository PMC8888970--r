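---
title: "Detecting gene fusions in exome and panel DNA alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene fusions in exome and panel DNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene fusions — hybrid genes produced by translocations, deletions or
inversions — are recurrent drivers in both hematological and solid tumors
(PML-RARA in acute promyelocytic leukemia, CBFB-MYH11 in AML subtype M4Eo,
TMPRSS2-ERG in roughly half of prostate cancers). Most fusion callers work
on RNA-seq, where splicing concentrates the junction signal into mature
transcripts. Whole-exome sequencing (WES) and targeted panels, however, are
what clinical pipelines routinely produce, and they carry fusion evidence
too — as long as the genomic breakpoint lies in or near a captured exon.
`wesfusion` detects fusions directly from DNA read alignments, so existing
WES/panel BAMs can be mined without additional sequencing.

## Evidence model

The caller consumes a coordinate-sorted SAM/BAM and a GTF gene model, and
looks for two complementary kinds of evidence:

* **Discordant read pairs** — mates that map inside two different genes,
  spanning (but not crossing) the junction of a fused DNA molecule.
* **Split reads** — single reads whose alignment is chimeric: a
  soft-clipped primary alignment in one gene plus a supplementary alignment
  (SAM `SA` tag) placing the clipped bases in another gene. These cover the
  breakpoint directly and are the stronger evidence; the junction is read
  off the clip boundary.

Records below mapping quality 30 are discarded up front, on every segment
(both mates, and supplementary alignments). Duplicate-flagged records are
dropped so PCR stacks cannot inflate support at deep panel coverage;
secondary alignments are ignored.

Discordance is decided by *gene assignment*, not by the aligner's
proper-pair flag: a pair is discordant when the two mates' overlapping gene
sets are disjoint. The proper-pair flag depends on insert-size calibration
of the aligner, while the fusion definition is intrinsically gene-centric.
Gene assignment uses the full gene span, introns included, because panel
and exome captures routinely produce reads in intronic flanks next to
targeted exons — exactly where DNA breakpoints sit.

### Fusion equivalence classes

A DNA read does not identify a transcript, only a locus, so each mate is
compatible with every transcript of its gene whose span covers the
alignment. The *fusion equivalence class* (FEQ) of a discordant pair is the
Cartesian product of the two mates' transcript sets, restricted to
cross-gene combinations: a mate consistent with 2 transcripts paired with a
mate consistent with 3 yields 6 candidate fusion transcripts. Classes with
identical member sets are merged and their supporting reads pooled. The FEQ
thus records how reads are shared among candidate fusion transcripts, and
gene-level candidates are aggregated from it.

Support is counted in deduplicated read-pair units: at most one unit per
(read name, gene pair), and a read contributing both a split and a
discordant signal counts once, in the split column. For every candidate,
`n_total = n_discordant + n_split` by construction.

### Breakpoints and orientation

DNA evidence alone cannot always orient a fusion, so gene pairs are
canonicalized by (chromosome, gene start). When split reads exist, the
breakpoint on each side is the per-side median of the split junctions, with
ties resolved to the smaller coordinate (lower-median), and orientation is
inferred from the clip geometry: a clip at the 3' end of a plus-strand
segment marks that gene as the upstream partner. Discordant-only candidates
fall back to the innermost mate ends and report orientation `unknown`.

## Filter cascade

Candidate-level filters are pure predicates, so the surviving set is
independent of application order; every rejected candidate records all the
filters it failed.

| filter | default | rationale |
|---|---|---|
| chromosome whitelist | 1–22, X, Y | removes mitochondrial/scaffold artifacts |
| protein-coding biotype | required | fusion partners of interest are coding genes |
| same-chromosome distance | ≥ 10 kb nearest-edge gap | removes read-through neighbours and local artifacts |
| minimum support | 1 read-pair unit | deep panels make single-unit evidence meaningful |
| genes per split read | ≤ 2 | multi-gene split alignments are multi-mapping noise |
| split-mate non-overlap | > 20 bp | overlapping split mates must contribute independent footprint |

Two rules operate at the split-read level and run *before* candidate
aggregation, so a discarded split can never rescue a support count. The
10 kb distance boundary is inclusive (a gap of exactly 10,000 bp passes,
measured end-of-left-gene to start-of-right-gene); the non-overlap rule is
strict (21 bp passes, 20 fails). Genes whose biotype is unknown (a GTF
without biotype attributes) fail the coding filter unless `assume_coding`
is set — the conservative default.

Discordant-only candidates are accepted by default (`require_split = FALSE`):
split-only candidates demonstrably occur in real data, and symmetric
treatment of the two evidence types maximizes sensitivity at panel depth;
`require_split` exists for stricter operation.

## The paralog filter

Paralogous genes with near-identical sequence are the dominant source of
false fusion calls: reads from one paralog align cleanly into the other and
masquerade as discordant evidence. `wesfusion` detects paralog pairs by
simulation: every transcript at least one read-length long emits
`sim_reads_per_tx` (default 10,000) error-free single-end reads at
uniformly random positions, and a read "maps" to another transcript when
its sequence occurs exactly as a substring there. This exact-occurrence
model is the idealization of an aligner on error-free reads; it is
deterministic, dependency-free and directly measures the quantity of
interest — sequence sharing. Transcripts of different genes are *sharing*
when either directed sharing fraction reaches `paralog_share_frac`
(default 0.5; an absolute `min_shared_reads` alternative is provided), and
a gene pair is paralogous as soon as any cross-gene transcript pair shares.
Candidates on paralogous pairs are rejected with the `paralog` flag. The
0.5 default is a deliberate midpoint: exact duplicates share ~100% of
reads, unrelated sequences share none, and partial-homology pairs fall on a
continuum that the threshold cuts conservatively; it is exposed in the
configuration. A computed paralog set can be cached as a two-column TSV and
reused.

## Synthetic data

The fixture generator makes the entire pipeline testable without external
data. `make_toy_reference()` builds random-sequence chromosomes carrying
non-overlapping multi-exon protein-coding genes (defaults: 4 genes of
~2.1 kb with four 300 bp exons, two transcripts each, on two chromosomes),
with an optional exact-duplicate gene pair for paralog tests.
`plant_fusion_reads()` draws paired-end fragments (truncated-normal insert,
mean 350 bp, sd 50 bp; 100 bp reads — the read geometry of the cohorts the
method targets) from the wild-type regions and from a fused allele joined
at the chosen breakpoints, at a configurable tumor fraction (default 0.5)
and mean coverage. Junction-crossing reads are emitted exactly as an
aligner would: soft-clipped primary plus supplementary record with
reciprocal `SA` tags, consistent flags and mate fields. Every read carries
a ground-truth label, so the number of recoverable split reads is known in
advance.

What the simulator deliberately does **not** model: base-call errors
(classification logic, not alignment robustness, is under test; an error
rate of zero makes ground truth exact), capture/GC bias, microhomology or
short insertions at junctions, and multi-mapping ambiguity. Passing tests
therefore demonstrate the correctness of extraction, classification,
aggregation and filtering on faithful alignments — not robustness to
aligner noise on degraded libraries.

`subsample_alignments()` keeps whole read pairs (with their supplementary
records) using one uniform draw per read name, so the kept set at a
smaller fraction is a subset of the kept set at a larger fraction under the
same seed. Per-pair (not per-record) subsampling keeps evidence units
intact, which is what support counting needs; the nesting makes
coverage-titration curves monotone by construction within a replicate.

## Worked scales and numerical choices

The test-suite and acceptance runs use these problem sizes, chosen so every
property is exercised at desk scale: toy references of 4–6 genes,
planted-fusion samples at 30–150x with ~10 kb of captured sequence, a
coverage-titration ladder that subsamples a 1500x sample down the published
design (10%, 5%, 2%, 1%, 0.5% — i.e. 150x to 7.5x), and paralog simulations
at 500–1,000 reads per transcript (the detection statistic is a fraction,
so it is scale-free; the full 10,000 default simply tightens it).

Other numerical decisions:

* Coordinates are 1-based inclusive everywhere (the GTF convention); SAM
  positions already use it, and interval arithmetic never mixes systems.
* Lower-median for breakpoint ties keeps output deterministic.
* The MAPQ gate applies to both mates and to supplementary segments — the
  conservative reading of a per-read threshold.
* No orientation (FR/RF) constraint is imposed on discordant mates: panel
  rearrangements include inversions, which flip strand geometry.
* Candidate tables are sorted (support descending, then gene pair) and
  carry a configuration hash, so identical inputs give byte-identical
  output.

## Known limitations

* A fusion whose breakpoints lie deep in untargeted introns produces no
  captured reads and is undetectable from exome data — a physical limit of
  the assay, not of the caller.
* Exact-substring paralog mapping ignores near-identical paralogs
  diverged by more than zero mismatches per read; the share threshold
  partially compensates, and an external aligner can be substituted by
  supplying a precomputed paralog TSV.
* The caller reports gene pairs, not base-resolution structural-variant
  records (no VCF BND output).
* Split detection relies on the aligner emitting supplementary alignments
  or `SA` tags; alignments produced without chimeric-read support yield
  discordant-pair evidence only.
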