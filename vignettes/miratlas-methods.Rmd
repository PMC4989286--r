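---
title: "Methods: building and validating a miRNA tissue atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a miRNA tissue atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

miratlas implements the analysis stack behind a small-RNA tissue atlas of
the kind built for preclinical safety species such as the beagle dog:
harmonize mature miRNA annotation across species onto one genome,
quantify small-RNA reads per locus, classify tissue-enriched miRNAs,
and validate candidates by qPCR — including serum biomarker panels read
against clinical chemistry. Every stage can be exercised on synthetic
data with planted ground truth, so the whole pipeline is testable on a
desktop without any external downloads.

## Cross-species annotation harmonization

Mature miRNA catalogs are much deeper for human and rat than for most
other species, while mature sequences are strongly conserved across
mammals. The harmonizer exploits this in four steps:

1. **Load** mature sequences per species (`load_mature_fasta()`),
   uppercased and with U replaced by T.
2. **Consolidate** (`consolidate_sequences()`): one record per distinct
   sequence string, so a conserved miRNA is placed once; the full
   (name, species) membership is retained and a representative name is
   chosen by species precedence (target species first, then input
   order, ties broken lexicographically — so the target species' own
   names label loci whenever available).
3. **Place** (`align_exact()`): every exact occurrence of each sequence
   on both genome strands. Zero mismatches is a hard requirement — one
   substitution in a ~22 nt guide can change targeting, and the whole
   point of the harmonization is to transfer annotation only where the
   mature sequence is literally present. An `N` in the genome never
   matches. Sequences with more than `max_locations` (default 10)
   placements across both strands are promiscuous mappers (repeats,
   paralog families) and are excluded entirely; a palindromic sequence
   matching one site on both strands counts as two placements.
4. **Merge** (`merge_loci()`): placements on the same chromosome and
   strand that overlap, or lie within `gap_tolerance` bases, are
   clustered transitively, and each cluster becomes one locus spanning
   the union.

"Approximately the same location" is not a precise notion, so the merge
distance is a parameter. The default `gap_tolerance = 0` (overlap or
abutment only) is the most conservative reading: isoforms of one mature
arm overlap heavily, while the 5p and 3p arms of one hairpin are
separated by a loop of ~10–20 nt and should *not* be merged. Merging is
strand-aware by construction, since mature miRNAs are single-stranded
and sense-specific. `build_annotation()` composes the four steps and
emits a funnel report (records surviving each step) alongside BED6
(0-based half-open) and GFF3 (1-based) exports; internally the package
keeps 0-based half-open coordinates throughout.

## Quantification

Alignment itself is out of scope — reads arrive as BED-like placement
records (or SAM, with `NH` mapped to the placement count). A placement
contributes one count to a locus when it covers at least
`overlap_frac = 0.7` **of the locus length**. The denominator matters:
small-RNA reads and miRNA loci have similar lengths, and anchoring the
fraction to the locus makes the rule insensitive to untrimmed adapter
bases while still rejecting reads that merely clip a locus edge. The
alternative (`overlap_denominator = "read"`) is available. Reads with
more than 10 genomic placements count nowhere, mirroring the annotation
filter; placements that satisfy the rule for two abutting loci are
resolved to the larger overlap so each placement contributes at most one
count. Counting is strand-aware by default (small-RNA library protocols
preserve strand); `stranded = FALSE` is available for unstranded data.

RPM normalization divides by the reads assigned to miRNA loci in the
sample (columns then sum to exactly 10^6), with the total aligned-read
denominator selectable. Assigned reads is the default because the
library composition outside miRNA loci (degradation products, other
small RNA classes) varies strongly between tissues and would otherwise
leak into every miRNA's value.

## Tissue-enrichment classification

Only loci with a tissue-median RPM above 100 in at least one tissue are
candidates. For each candidate locus and each tissue:

* **fold change** = (tissue median RPM + 1) / (pooled median RPM of all
  other samples + 1). The pseudocount of 1 RPM keeps folds finite for
  zeros and is negligible at the 100 RPM candidate floor.
* **p-value**: one-sided Wilcoxon rank-sum of the tissue's samples
  against all other samples. Enrichment is directional, hence
  one-sided; a two-sided option exists. With 12 or fewer total samples
  and no ties the exact permutation distribution of the rank-sum
  statistic is used; otherwise midranks with the normal approximation
  and tie correction (no continuity correction). The switch point is
  chosen so that the atlas design (5 tissue vs ~75 other samples)
  always takes the deterministic approximation.
* **q-value**: Benjamini–Hochberg step-up, by default per tissue
  (each tissue is its own testing family across candidate loci); a
  global option exists.

A record is **TE** (tissue enriched) when fold > 5 *and* q < 0.05.
**HTE** (highly tissue enriched) is a deliberately harsher, p-value-free
criterion: the tissue median must exceed 5 times the *maximum value
observed in any individual sample* of any other tissue, and the locus
must be detected (tissue median RPM > 100) in at most 2 tissues. The
per-record class is `HTE1` when HTE holds in exactly one tissue for the
locus, `HTE2` for two, otherwise `TE` if TE holds, else `none`. Under
the literal sample-maximum comparator two tissues can essentially never
both be HTE for one locus (each median would have to exceed 5 times the
other), so `HTE2` is a boundary class; a median-based comparator
(`hte_comparator = "tissue_median_max"`), under which HTE2 is
attainable, is provided.

Sample-level QC follows the atlas convention of squared Spearman rank
correlations between RPM profiles (within-tissue means should sit well
above between-tissue means); constant profiles have undefined rank
correlations and are flagged and excluded from means. Reference-gene
scoring ranks loci for use as qPCR normalizers: stable references have
CV% < 10 and SD ≤ 1 of log2 tissue medians, and mean tissue-median RPM
above 100.

## qPCR validation and serum panels

Technical replicates are averaged after censoring Ct values strictly
above 38 cycles (the boundary value 38.0 is retained); measurements
whose replicates are all censored stay censored. ΔCt subtracts the
arithmetic mean of the reference targets' mean Cts in the same sample —
equivalent to a geometric mean on the linear scale — and relative
expression is 2^(−ΔCt). Cross-platform agreement is summarized by OLS
of log2 relative expression on log2(RPM + 1); the +1 handles zeros in
the sequencing axis.

Serum panel studies join per-animal time courses of panel miRNAs with
ALT/AST chemistry. When no reference set is given (circulating
reference miRNAs are notoriously unstable under treatment), ΔCt is
taken against the per-sample *plate median* of all non-censored
targets; the median, unlike the mean, is robust to the panel's own
responding targets dragging the baseline. `panel_correlate()` reports
per-animal OLS r² of −ΔCt (log2-scale expression; linear `rel_expr`
selectable) against the analyte, with animals under 3 usable timepoints
flagged not-evaluable. An r² on six timepoints of a flat target is
noisy by construction, so interpretation (and the package's own tests)
couples it with the ΔCt dynamic range: a liver-injury responder shows
both high r² and a multi-cycle ΔCt elevation, while specificity
controls are judged by staying inside a one-cycle noise band.

## The synthetic-data generator

`simulation_config()` defaults encode the atlas design: 16 tissues × 5
replicates, ~10^6 assigned reads per sample, 300 loci of 18–25 nt on a
toy multi-chromosome genome, three species with conservation fractions
(half conserved in all three, 30% in two, 20% species-unique), one
sequence planted 11 times to exercise the multi-mapper filter, 20
planted single-tissue HTE loci at fold 50, 30 planted TE loci at fold
10, negative-binomial counts with dispersion 0.1
(Var = μ + 0.1 μ²), a Ct model linear in log2 expression
(Ct = 36 − log2 expr + N(0, 0.15), 40-cycle instrument ceiling),
and a proof-of-concept panel with 2 injured and 4 control animals over
days 1/7/14 × pre/post dose. Planted HTE baselines sit below the
detection cutoff (10–40 RPM) so their enrichment is confined to the
planted tissue; planted TE baselines (50–500 RPM) keep the fold
estimate above threshold after pseudocounting. Each generator derives
its RNG stream from the base seed plus a fixed offset, so outputs are
byte-reproducible independently of call order.

The generator emulates the *statistical* structure the analysis
assumes — replicated tissues, overdispersed counts, multiplicative
enrichment, Ct linear in log abundance, injury driving miRNA and
enzyme elevation through a shared latent trajectory. It does not model
sequencing error, adapter artifacts, isomiR heterogeneity, cross-
hybridization, or real biological covariance between tissues; passing
recovery tests therefore demonstrates correctness of the procedures
under the stated model, not performance on real libraries.

## Numerical and scale choices

Degenerate inputs are handled explicitly: fully tied rank-sum input
returns p = 1; equal multisets carry no one-sided evidence (p = 0.5 at
the null mean of the statistic); all-zero library columns yield zero
RPM with a warning; constant profiles are excluded from correlation
means; ties in locus naming get deterministic `-locN` suffixes in
coordinate order. The pipeline runs enrichment on the full simulated
16 × 5 count matrix while exercising read-level counting on a subset of
samples with alignment files (default 4 at 2 × 10^4 reads) — locus-level
counts are the quantity the enrichment model consumes, and simulating
full read placements for 80 samples would add bulk without adding
coverage. Test and recovery runs use 30–300 loci and library sizes of
10^5–10^6; these sizes keep the complete suite in the minutes range
while preserving the design shape (replication, depth-to-dispersion
ratio) that the statistics depend on.

## Limitations

* The TE/HTE thresholds (fold 5, q 0.05, detection 100 RPM) are
  conventions, not estimates; they are exposed in
  `enrichment_config()` and results should be read relative to them.
* No dispersion modeling or shrinkage is performed — the Wilcoxon test
  is rank-based and needs replicate counts per tissue (≥ 2, ideally 5).
* The harmonizer transfers annotation only for exactly conserved mature
  sequences; diverged homologs are invisible to it by design.
* Reference-free panel normalization assumes most panel targets are
  non-responders; panels dominated by responders need an explicit
  reference set.
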