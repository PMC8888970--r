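# wesfusion

Fusion gene detection from whole-exome and targeted-panel **DNA** sequencing
alignments.

Most fusion callers require RNA-seq. Clinical pipelines, however, routinely
produce exome and panel BAMs, and those alignments carry fusion evidence
whenever a genomic breakpoint falls in or near a captured exon. `wesfusion`
mines that evidence directly: it is aimed at cancer genomics groups who want
to validate RNA-seq fusion calls in matched DNA (PML-RARA, CBFB-MYH11 in
AML), or call recurrent fusions such as TMPRSS2-ERG from deep targeted
panels, without additional sequencing.

## Method

From a coordinate-sorted SAM/BAM and a GTF gene model, the pipeline:

1. **Extracts evidence.** Records with MAPQ < 30, duplicates and secondary
   alignments are dropped. Two evidence types remain:
   *discordant pairs* — mates mapping inside disjoint gene sets, spanning a
   junction — and *split reads* — a soft-clipped primary alignment plus a
   supplementary alignment (`SA` tag) placing the clipped bases in another
   gene, covering the junction directly.
2. **Builds fusion equivalence classes (FEQs).** A DNA mate is compatible
   with every transcript of its gene covering the alignment; the FEQ of a
   discordant pair is the cross-gene Cartesian product of the two mates'
   transcript sets (2 × 3 transcripts → 6 candidate fusion transcripts).
   Classes with identical members merge, pooling their supporting reads.
3. **Aggregates gene-pair candidates** with deduplicated support counts
   `n_total = n_discordant + n_split` (a read supporting a pair both ways
   counts once, as split), split-junction-median breakpoints and
   clip-geometry orientation.
4. **Filters.** Chromosome whitelist (1–22, X, Y), protein-coding biotype,
   ≥ 10 kb same-chromosome distance, minimum support (1 unit), ≤ 2 genes
   per split read, > 20 bp non-overlap for overlapping split mates, and a
   **simulation-based paralog filter**: 10,000 uniform error-free reads per
   transcript are mapped back by exact substring occurrence; gene pairs
   whose transcripts share ≥ 50% of reads are rejected as paralogs.

A synthetic-data module (`make_toy_reference()`, `plant_fusion_reads()`,
`subsample_alignments()`, `sensitivity_curve()`) generates ground-truth
labeled planted-fusion samples and coverage titrations, so every stage is
verifiable offline. See `vignettes/wesfusion-methods.Rmd` for the full
model, parameter rationale and limitations.

## Worked example

Plant an inter-chromosomal fusion between two toy genes at 150x with tumor
fraction 0.5, then call it:

```r
library(wesfusion)

ref  <- make_toy_reference(n_genes = 4, seed = 7)
spec <- fusion_spec("G01", "G02", break_a = 5700, break_b = 5700,
                    fraction = 0.5)
pl   <- plant_fusion_reads(ref, spec, coverage = 150, seed = 1)

res <- run_pipeline(pl$sam, ref$ann, wes_config())
res
#> fusion_calls: 1 passed, 0 rejected
#>   gene_a gene_b chrom_a pos_a chrom_b pos_b n_discordant n_split n_total
#> 1    G01    G02    chr1  5700    chr2  5700          156      84     240
#>   orientation
#> 1        a_up
```

Exactly the planted pair is called, with both breakpoints recovered at the
planted coordinates (chr1:5700 / chr2:5700): 156 discordant read pairs span
the junction, 84 split reads cover it (240 support units in total), and the
clip geometry orients G01 as the upstream partner. `write_fusion_table()`
serializes the call table with a provenance header;
`res$rejected$filter_flags` explains every removed candidate.

A shell front end wrapping the same functions ships in
`inst/cli/wesfusion.R` (`call`, `simulate`, `subsample`, `compare`
subcommands).

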