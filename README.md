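# v2gmap

Variant-to-gene (V2G) mapping through 3D chromatin structure, for
regulatory genomics of GWAS loci. Most autoimmune risk variants are
non-coding and frequently skip the nearest gene; `v2gmap` nominates
effector genes by requiring that a candidate causal variant (i) belongs to
the 95% credible set of its association signal, (ii) falls in open
chromatin (ATAC-seq consensus peaks), and (iii) either sits in a gene's
promoter window (−1500/+500 bp around a TSS) or sits in an open-chromatin
region at a Hi-C loop anchor whose partner anchor touches a promoter.

The statistical core:

* fine-mapping by approximate Bayes factors
  `ABF = sqrt(V/(V+W)) · exp(z²W / 2(V+W))` with `z = Φ⁻¹(1 − p/2)`,
  posteriors `PP_i = BF_i / Σ_j BF_j`, and the minimal posterior-ordered
  prefix with `Σ PP ≥ 0.95`;
* consensus merging of 1/2/4 kb loop calls (finest kept; a coarser call is
  absorbed when a kept loop overlaps it at both anchors) and timepoint
  union with per-stage support flags;
* benchmarking: precision/recall against curated truth sets, set
  concordance, a 1 Mb-window permutation test with empirical
  `p = (1 + #{null ≥ obs})/(1 + N)`, the one-sided continuity-corrected
  two-proportion test, and BH correction;
* k-means trajectory clustering with a log-WCSS elbow and an immune
  expression-specificity score (whole blood + spleen over other tissues);
* a planted-ground-truth simulator that makes the whole pipeline testable
  offline — every planted variant-gene pair is recoverable by
  construction, and nothing else is.

## Worked example

```r
library(v2gmap)

cfg    <- sim_config(seed = 7)                 # the stated synthetic world
genome <- simulate_genome(cfg)
land   <- simulate_regulatory_landscape(cfg, genome)
gwas   <- simulate_gwas(cfg, genome, land)

res <- run_v2g(gwas$stats, land$ocrs, land$loops, genome$genes,
               chrom_lengths = setNames(genome$chrom_length, genome$chrom))
```

This prints nothing by itself; the summaries are explicit calls:

```r
res$report$mean_before; res$report$mean_after
#> [1] 13.14        # mean credible-set size per sentinel...
#> [1] 0.6          # ...after the open-chromatin constraint

s <- degree_and_distance(res$pairs)
c(s$n_pairs, s$n_variants, s$n_genes)
#> [1] 30 30 30
s$distance_median
#> [1] 104924       # median variant-to-TSS distance, bp

attr(classify_nearest(res$accessible, res$pairs, res$genes_used), "counts")
#>  no_gene  nearest_only  nearest_plus_distal  distal_only
#>        0            10                    0           20

attr(stage_sharing(res$pairs), "tier_counts")
#>  all_stages  two_stages  one_stage  unsupported
#>          11          12          7            0
```

Reading: the accessibility filter shrinks credible sets from ~13 variants
per sentinel to well under one on average (only causal variants were
planted in open chromatin); the pipeline recovers all 30 planted
variant-gene pairs and nothing else; two-thirds of linked variants skip
the nearest gene entirely, and about a third of nominated genes are
supported at every activation stage — the panel of summaries the method
reports on real data.

Benchmarking against a truth list:

```r
pr <- precision_recall(predicted_genes, read_truth_set("truth_genes.txt"))
# e.g. an overlap of 71 genes against a 449-gene truth set:
round(100 * pr$recall)
#> [1] 16
```

## Command line

```sh
exec/v2gmap simulate  --seed 7 --out fixture/
exec/v2gmap credset   --stats fixture/sumstats.tsv --ocr fixture/ocrs.tsv --out cs.tsv
exec/v2gmap v2g       --stats fixture/sumstats.tsv --ocr fixture/ocrs.tsv \
                      --loops fixture/loops.bedpe --genes fixture/genes.tsv \
                      --out pairs.tsv --summary summary.json
exec/v2gmap benchmark --pred pairs.tsv --truth fixture/truth_genes.txt
```

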