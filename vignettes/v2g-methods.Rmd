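---
title: "Methods: variant-to-gene mapping via chromatin loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-to-gene mapping via chromatin loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v2gmap)
```

## The problem

Most GWAS risk variants for autoimmune disease are non-coding, and the gene
they regulate is often not the nearest one. `v2gmap` implements a
variant-to-gene (V2G) strategy that combines three data layers measured in
the same cell state (here, naive CD4+ T cells before and at 8 h / 24 h
after anti-CD3/CD28 activation):

1. **Statistical fine-mapping** of each association signal into a 95%
   credible set of candidate causal variants;
2. **Open chromatin** (ATAC-seq consensus peaks, OCRs) as a constraint:
   only variants falling in accessible regulatory DNA are retained;
3. **Chromatin loops** (Hi-C calls at 1/2/4 kb resolution): an accessible
   variant is linked to a gene when its OCR sits at a loop anchor whose
   partner anchor overlaps the gene's promoter, or when the OCR itself lies
   in the promoter window.

## Fine-mapping model

For each variant of a signal, the two-sided p-value is converted to
$z = \Phi^{-1}(1 - p/2)$ and then to an approximate Bayes factor. The
default is the Wakefield-style shrinkage form

$$\mathrm{ABF} = \sqrt{\frac{V}{V+W}}\;
  \exp\!\left(\frac{z^2}{2}\,\frac{W}{V+W}\right),$$

with sampling variance $V = 1$ (the z-score scale, used when standard
errors are absent) and prior effect variance $W = 0.04$ (prior SD 0.2).
The upstream study cites its established credible-set method without
reproducing formulas, so these defaults are this package's documented
choice, recorded in output metadata; a simpler `z2` mode
($\mathrm{BF} = e^{z^2/2}$) is available. Posterior probabilities are the
normalized Bayes factors within the signal, computed in log space so
genome-wide-significant hits cannot overflow; p-values are floored at
1e-300 before the quantile transform.

Variants are sorted by decreasing posterior probability (ties broken by
ascending p-value, then position, then variant id) and accumulated until
the cumulative posterior reaches the coverage target (default 0.95). The
threshold is inclusive and evaluated with a 1e-12 tolerance so that exact
boundary sums (e.g. 19 variants of posterior 0.05) keep the minimal set.

The open-chromatin constraint is a *filter*: posteriors are not
renormalized afterwards and the 95% threshold is not re-applied, because
the workflow reads as sequential filtering and renormalization would change
the reported set sizes. A `renormalize_after_filter` flag supports
sensitivity analysis.

## Coordinates, promoters, loops

All internal coordinates are 0-based half-open; BED is native, GTF and
summary-statistic positions are converted on read and back on write.
Variants are 1-bp intervals `[pos, pos+1)`.

The promoter window is **-1500/+500 bp around each TSS**, strand-aware by
default (1500 bp upstream of the direction of transcription); the source
description does not say whether the window follows strand, so
`strand_aware = FALSE` reproduces the orientation-blind reading. Genes keep
their full TSS list — multi-TSS support matters because most human genes
have several alternative start sites — and variant-gene distances are the
minimum over that list.

Loop calls arrive per resolution (1, 2, 4 kb) and per timepoint.
Consensus merging processes resolutions fine to coarse: every 1 kb loop is
kept, and a coarser call is added only when no kept loop overlaps it at
*both* anchors (paired anchor1–anchor1 / anchor2–anchor2, half-open, no
padding; an `--anchor-slop` style parameter was deliberately not added
because the source states no padding rule). Timepoint union applies the
same both-anchor rule, keeping the finest representative and flagging every
supporting timepoint. The source is ambiguous about whether stages or
resolutions merge first; the default is resolutions-then-stages with the
other order available in `consensus_loops()`.

A contact is supported at a timepoint only when a supporting loop is
present *and* the OCR is accessible at that timepoint. Contacts whose OCR
overlaps the target gene's own promoter window are classed
`promoter-proximal`, others `distal`.

## Nomination and descriptive statistics

A variant-gene pair is nominated with evidence `promoter_proxy` (variant in
an OCR overlapping the gene's promoter window) and/or `distal_contact`
(variant in the OCR of a promoter-interacting contact); a pair supported by
both carries both tags on one record, keeping per-pair statistics
unduplicated. The gene universe defaults to protein-coding genes.
Genes-per-variant is reported both over all evidence and distal-only,
because the source's per-variant degree could be read either way. The
nearest-gene classification partitions accessible variants into
`no_gene` / `nearest_only` / `nearest_plus_distal` / `distal_only`, with
"nearest" the minimum-TSS-distance gene (ties by gene id). Stage sharing
assigns each nominated gene the number of supporting timepoints.

## Benchmarking and enrichment

Precision is `|P ∩ T| / |P|` and recall `|P ∩ T| / |T|` after upper-casing
symbols; concordance between two prediction sets reports both directional
fractions and Jaccard because the "percent overlap" denominator is not
stated in the source. The permutation test replaces each comparison pair's
gene with a uniform draw from genes having a TSS within 1 Mb of the
sentinel (10,000 iterations by default), and reports
$p = (1 + \#\{null \ge obs\})/(1 + N)$ — the add-one form cannot return 0.
Draws are per-pair independent with replacement by default
(`sample_without_replacement` available). The proportion enrichment test is
the continuity-corrected one-sided two-sample proportion test (R's
`prop.test`, the tool used upstream); the test suite checks it against an
independently coded pooled-proportion z formula. Family-wise correction is
Benjamini–Hochberg.

Because the observed overlap count is integer-valued, the empirical
p-value is discrete and cannot be exactly uniform under the null; the
calibration suite therefore checks the randomized probability integral
transform $u = (\#\{null > obs\} + U\,(\#\{null = obs\} + 1))/(N+1)$,
which is exactly U(0,1) when the observed statistic is exchangeable with
the null draws.

## Expression dynamics

Differential-gene trajectories (differential calling itself is an upstream
count-model step and is consumed, not reimplemented) are per-gene z-scored
and clustered by k-means (>= 10 restarts, best inertia, fixed seed). The
cluster count is chosen by the elbow criterion on the within-cluster sum
of squares, **computed as the maximum second difference of log(WCSS)**.
The raw-WCSS second difference was tried first and rejected: for k-means
on row-standardized 3-timepoint trajectories (which lie on a circle after
standardization) successive merge costs decrease with k, so the raw
curvature is maximized at k = 2–3 for *every* planted geometry tested,
including the well-separated 5-archetype fixture; the log scale locates
the kink of the curve rather than its overall convexity and recovers both
the 2-archetype and the 5-archetype planted truths reliably. Raw mode
remains available (`elbow_scale = "raw"`). Ties break toward smaller k.
Per-gene quality is the Pearson correlation to the assigned centroid.

The immune expression-specificity score is the summed median expression
over whole blood and spleen divided by the sum over all other tissues
(GTEx v8-style input); it is scale-invariant and flagged undefined when
the denominator is zero.

## The synthetic world

The generator plants a complete, reachable ground truth on one 10 Mb
chromosome: 200 genes (TSS spacing >= 5 kb, 1–3 TSS, mixed strands,
90% protein-coding), 1000 consensus OCRs (200–1000 bp, per-timepoint
accessibility, >= 2 replicates), background loops at all three resolutions
and timepoints, and 50 association signals averaging 14 variants each —
60% of sentinels carry a causal variant (z centered at 6, unit noise by
default) planted inside a promoter-connected OCR (30% promoter-proxy, 70%
distal with a bin-aligned loop, occasionally duplicated at a coarser
resolution to exercise consensus merging). Proxy z-scores decay with
distance as $\rho = e^{-d/20\,\mathrm{kb}}$ — a distance-decay emulation,
not a haplotype model, which is a documented limitation (no realistic LD
blocks, no allele frequencies, no multi-causal signals).

Placement rules make the planted truth exhaustive: planted elements avoid
all other promoter windows and each other, background loop anchors avoid
every promoter window, and every non-causal variant is placed outside all
open chromatin. Consequently, with noise off, the pipeline must recover
exactly the planted pair list — a green end-to-end test establishes the
plumbing and the evidence predicates, *not* performance on real data with
LD leakage, shared enhancers and imperfect loop calls.

The truth-set generator sizes overlap and decoys so the perfect predictor
hits the configured precision/recall exactly, and errors on designs that
are not achievable in integer arithmetic. With the default world (50
sentinels, 60% causal = 30 effectors) the 0.25/0.5 design needs an
effector count divisible by 4, so exact-design checks use a 40-sentinel
world (24 effectors: overlap 6, truth 12); the fixture writer instead
rounds to the nearest feasible design with a warning. The expression
fixture plants five trajectory archetypes as equally spaced directions on
the standardized-trajectory circle with sample noise SD 0.2, three
replicates per timepoint.

## Numerical choices, in one place

* log-space Bayes factors and log-sum-exp posteriors; p floor 1e-300;
* inclusive coverage threshold with 1e-12 slack;
* deterministic tie-breaks everywhere (posterior ties by p, position, id;
  nearest-gene ties by gene id; elbow ties toward smaller k);
* unsorted interval inputs are sorted internally with a warning rather
  than rejected;
* chromosome names match by exact string after optional `chr`-prefix
  normalization.

## Known limitations

Single-causal-variant fine-mapping only (no LD-matrix conditioning or
SuSiE-style multi-signal sets); LD emulation by distance decay; no
liftover, sequence or alignment handling; differential expression and loop
calling are consumed upstream, never recomputed.
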