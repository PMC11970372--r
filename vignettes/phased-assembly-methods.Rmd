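---
title: "Methods: phased-assembly QC, haplotype comparison and candidate-gene mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phased-assembly QC, haplotype comparison and candidate-gene mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasekit)
```

phasekit implements the computational accounting that accompanies a phased
(haplotype-resolved) diploid genome assembly: how complete is each haplotype,
where does the assembly collapse repeats, how do the two haplotypes differ
structurally, which chromosome pair behaves like a ZW sex pair, and — on the
functional side — which members of a candidate enzyme family co-express with a
known biosynthesis pathway. Every procedure is exercised on synthetic data in
which the truth is planted, so each stage has a parameter-recovery test rather
than a visual sanity check.

## Coordinate conventions

All internal coordinates are 0-based half-open (the BED/PAF convention).
Human-readable reports are 1-based inclusive. The conversion lives in exactly
one pair of functions, `to_report_coords()` / `from_report_coords()`, which
shift every `*start` column by one; a half-open `end` equals the 1-based
inclusive end, so `end` columns are untouched.

## Assembly QC

A **gap** is a maximal run of `N` of length at least `min_n_run` (default 10).
Published assembly tables rarely define "gap"; a threshold of 10 avoids
counting isolated ambiguous bases as gaps while catching every placeholder
run. A **telomere** is called at a chromosome end when at least `min_copies`
(default 10) occurrences of the telomeric repeat (default the plant motif
`TTTAGGG`, or its reverse complement `CCCTAAA`, so both strand orientations
are recognised) fall within the terminal window (default 10 kb). A chromosome
is **T2T** when both ends are telomeric and the gap count is zero.

The **NX curve** uses the first-cumulative-reach convention of common
assembly-statistics tools: NX is the length of the contig at which the
cumulative sum of descending-sorted contig lengths first reaches X% of the
total. **QV** converts to expected base errors per Mbp as
$10^{-QV/10} \times 10^6$ (QV 60 is exactly 1 error per Mbp). The
**anchoring rate** is the anchored fraction of the total assembly size; the
published arithmetic for the assembly this package's fixtures describe is
consistent with total assembly size (not total contig length) as the
denominator, and that is the definition implemented.

Ratios and percentages are kept at full precision internally and rounded
half-up to the published precision only in reports.

## Collapse detection and corrected lengths

A collapsed region is present in two copies in the underlying genome but
assembled once, so HiFi read depth doubles over it. The caller takes a
pre-windowed depth track (window default 10 kb in the toy configuration; the
statistic is the same at any window), estimates the single-copy baseline as
the **modal** window depth (tallest histogram bin at Freedman–Diaconis
widths — robust against the right tail the collapsed windows themselves
create), flags windows at or above `factor` × baseline (default 1.75: a
2-copy region sits near 2×, and 1.75 tolerates noise while staying above any
plausible 1-copy excursion), merges adjacent flagged windows, and estimates
copies as `round(depth / baseline)` clamped to ≥ 2 (below 1.5× a window
cannot be flagged at all, so a 1-copy estimate cannot arise).

Corrected chromosome length is assembled length plus the extra length the
collapse calls imply (`length × (copies − 1)`). Haplotype length differences
are computed on corrected lengths, and each percent difference uses that
haplotype's own corrected length as denominator (which is why the two
percentages differ slightly). Sex-candidate ranking sorts pairs by percent
difference after excluding pairs whose difference is explained by
interchromosomal translocations (taken from the SV calls); in the top pair
the longer haplotype is labelled W, the shorter Z — the assembled individual
is assumed female, as seed set demonstrates in a dioecious conifer.

## Structural-variant classification

Input is haplotype-to-haplotype alignment blocks (PAF; query = haplotype 2,
target = haplotype 1). A **syntenic backbone** is chained per chromosome
pair: the maximum-weight (block-length-weighted) subset of plus-strand blocks
collinear in both coordinate systems — a longest-increasing-subsequence
dynamic programme — restricted to mutually best-covering chromosome pairs, so
a lone cross-chromosome block can never be its own backbone. Classification
against the backbone:

* minus-strand blocks → **INV**;
* blocks aligning a query chromosome to a target that is not its backbone
  partner → **TRANS**;
* off-backbone plus-strand blocks whose target interval is ≥ 50%
  backbone-covered → **DUP** (the 50% is a documented, tunable choice; no
  published criterion exists);
* gaps between consecutive backbone blocks present on only the query side →
  **INS**, only the target side → **DEL**.

Candidates shorter than `min_sv_len` (50 bp, inclusive) are discarded.
Overlapping candidates are resolved deterministically by precedence
INV > TRANS > DUP > INS/DEL, longest first: a translocation's source gap
would otherwise double-report as a deletion, and a duplication's novel copy
as an insertion. Unaligned (nonhomologous) region fractions use a sorted-sweep
interval union, verified in tests against a per-base bitmap oracle.

## Coexpression mining

Expression values (TPM scale) are filtered (expressed at ≥ 1 TPM in ≥ 3
samples) and log-transformed (`log2(x + 1)`); Pearson correlation on this
scale is the field default for TPM panels (Spearman can be substituted by
transforming upstream — the matrix interface takes anything tabular). The
correlation matrix over the labelled genes (known pathway plus enzyme
family) is clustered by average-linkage agglomerative clustering on
`d = 1 − r`, cut into `k` clusters. The candidate module is the cluster with
the most known pathway genes (ties broken by the mean family-to-known
correlation inside the cluster), and its family members are the candidates.

When `k` is not supplied it is chosen by maximizing the mean silhouette width
over `k ∈ 2:max(20, n/3)`. The upper bound scales with the gene count by
design: the planted module is internally tight (pairwise r ≈ 0.8), so it
survives deep cuts intact, while decoy genes that attached to it through
chance correlation (at 40 samples the null correlation has sd ≈ 0.16) split
off as singletons only if the scan is allowed to cut deep enough. Capping the
scan at 20 clusters for ~174 labelled genes leaves those attachments in
place and costs about five points of precision; with the scaled bound,
20-seed mean recall/precision are ≈ 1.0 / 0.96.

The 11-gene-style **shortlist** formalizes an expert judgement (spread picks
over phylogenetic clades and chromosomal positions): clades are visited in
rounds by descending size and within each clade the gene maximizing the
minimum genomic distance to already-picked genes wins (different chromosome
counts as infinitely distant; remaining ties break by gene id). It is a
documented heuristic of this package, not a published method. The
**cluster-fraction** statistic (`gene_cluster_fraction()`) simply counts
family members inside one genomic region.

## Sex-biased expression scan

Within designated nonhomologous Z/W regions, a gene is sex-biased in a tissue
(default flower) when one sex expresses it at ≥ `tau_on` (default 1 TPM) and
the other at ≤ `tau_off` (default 0.1 TPM). The thresholds are configurable;
published heatmaps do not pin them down. Swapping the sex labels of the input
swaps every bias direction — a property the tests assert.

## Docking-pose filter

Docked conformations are kept when the Euclidean distance from the substrate
reactive atom to the iron of the iron-oxo centre is within 5 Å (inclusive)
and the docking score is negative. Which substrate atom is "reactive" is
deliberately the caller's choice when exporting the pose table; published
descriptions are ambiguous between a specific carbon and a centroid.

## The synthetic-data generator

`sim_config()` defines the study conditions at toy scale: 4 chromosome pairs
of 2 Mb, telomere arrays of 100 motif copies, two 500 bp gaps per chromosome
(none on `chr2_h1`, so exactly one chromosome is T2T), planted SVs (two
inversions, one translocation, one duplication by default), window 10 kb and
mean depth 30× (a scaled-down rendering of a 100 kb-window, ~72× HiFi depth
screen), and a 100 kb W-specific insertion on the sex pair. The expression
panel is 40 samples with a planted module of 16 known pathway genes plus 70
of 158 family genes at pairwise correlation 0.8 — the shape of the published
mining problem. These sizes keep the full simulate-and-recover loop in
seconds; the tests and the acceptance script state the problem sizes they
run at.

Design choices worth knowing:

* **Collapse lives only in the depth track.** The FASTA holds one copy —
  that is what "collapse" means; simulating reads would add cost without
  adding test power, since the published statistic is window-level.
* **Planted collapse is balanced per pair** (equal extra on both haplotypes,
  different positions): assembly collapse of a shared repeat explains
  *apparent* length asymmetry, which is exactly the corrected-length logic's
  premise. One-sided planted collapse would fabricate genuine asymmetry on
  non-sex pairs and make the planted sex pair unrecoverable by construction.
* **The sex insertion is recorded in truth as an INS structural variant** —
  it is one, and the SV classifier recovers it as such.
* **Alignment blocks are a deterministic projection of the truth** into PAF
  space (backbone offsets bookkept from the dual-coordinate SV table), not a
  re-alignment: inversions become minus-strand blocks, translocations
  cross-chromosome blocks, duplications two query blocks onto one target
  interval, and the sex insertion an alignment hole. Blocks under 50 bp are
  dropped, matching the classifier's floor.

What the generator does **not** emulate: sequencing error, read-level noise,
repeat-induced mis-alignment, segmental duplication families, partially
penetrant expression modules, or batch effects. Passing recovery tests
therefore demonstrate the correctness of the procedures under their stated
models, not robustness to every artefact of real data.

## Statistical framing of the recovery checks

Recovery guarantees are rates, and the toy genome is small: one toy run
holds ~14 collapsed windows, so a single missed boundary window (miss
probability ≈ 3.9% per 2-copy window at the 1.75× threshold and 10% depth
noise) swings a per-run sensitivity estimate by 7 points around a true rate
of 0.96–0.98. `run_pipeline()` therefore pools the collapse check over 20
seeded depth replicates and averages the module check over 20 seeded
expression replicates; the acceptance checks pool 100 and 20 replicates
respectively. Single-run results are still reported alongside.

Determinism: every generator takes an explicit seed and is byte-reproducible
under it; clustering, chaining, classification and ranking are deterministic
with documented tie-breaks (gene id, pair id, coordinate order).

## Known limitations

* The SV classifier is matched to the alignment-block taxonomy it is tested
  on; nested or overlapping real-world SVs are resolved by the precedence
  rule, not re-genotyped at base level.
* `modal_depth()` assumes single-copy windows dominate the track; a genome
  that is mostly collapsed would fool the baseline.
* The silhouette-selected `k` is a heuristic; pathological correlation
  structures can prefer degenerate cuts. `k` can always be fixed explicitly.
* Depth windows are assigned by midpoint, so collapse calls inherit window
  granularity; sub-window collapse boundaries are invisible by construction.

## A worked example

```{r example, eval = FALSE}
library(phasekit)
report <- run_pipeline(pipeline_config(seed = 1))
report
glance(report)
tidy(report$module_fit)
autoplot(report$module_fit)
plot_depth_track(simulate_depth_track(report$truth, seed = 2),
                 report$collapse_calls, report$depth_baseline)
```
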