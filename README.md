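# editpeaks

Inosine peak calling and ADAR1 isoform-dependency analysis for
modification-encoded enrichment sequencing of RNA.

## The problem

A-to-I RNA editing — deamination of adenosine to inosine by ADAR enzymes
in double-stranded RNA — is read as guanosine by sequencers, so edits
appear as A→G mismatches. Bead-enrichment assays capture
modification-bearing RNA fragments, encode the modification identity in a
read-embedded barcode (MBC), tag each molecule with a UMI, and sequence
the captured fraction alongside a non-enriched *solution control* from
the same library. Mixing in synthetic spike-in controls with known
modified/unmodified status puts the observed enrichment on an absolute
scale.

`editpeaks` turns mapped reads from such an experiment into:

1. **Modification peaks** per class (inosine, m6A), called from
   enrichment-vs-control coverage and scored for confidence;
2. **A-to-I editing sites** inside inosine peaks, from strand-aware
   pileup variant calls;
3. **Gene-feature annotation** of peaks (exon, intron, 5'/3' UTR,
   lncRNA) and the regional distribution of modified genes;
4. **Per-gene ADAR1 isoform-dependency categories**, from wild-type
   versus p150 / p150+p110 knockout peak scores.

A fully seeded synthetic-data generator plants peaks, editing rates,
spike-in recoveries and dependency categories, so every stage of the
pipeline is testable against ground truth.

## The model in brief

For each modification class and strand, with enrichment depth $e(p)$,
control depth $c(p)$, pseudocount $c_0$ and a class-local library-size
factor $s$ (ratio of genome-wide median depths), the signal is

$$x(p) = \log_2\frac{e(p) + c_0}{s\,c(p) + c_0},$$

smoothed by a centered moving average of width $w$. Peaks are local
maxima with topographic prominence at least $\pi_{\min}$, extended to
where the smoothed signal falls below (summit − prominence/2) or zero.
Fold enrichment is the peak's maximal smoothed enrichment depth over the
library-scaled mean control depth, divided by the spike-in enrichment
factor

$$\phi = \frac{\sum E_\text{mod} / \sum C_\text{mod}}
              {\sum E_\text{unmod} / \sum C_\text{unmod}}.$$

Peak confidence comes from a two-state Gaussian hidden Markov model
fitted to the binned smoothed signal; a peak's q-score is
$-10\log_{10}(1 - \bar\gamma)$ (capped at 100), where $\bar\gamma$ is the
overlap-weighted mean posterior of the enriched state over the peak's
bins. High-confidence peaks need q ≥ 13 and enrichment depth ≥ 5.

Editing sites are pileup columns inside inosine peaks with reference A
(or T for minus-strand genes, whose edits appear as T→C in
reference-forward coordinates), column depth strictly greater than 5,
and variant rate (alt reads / column depth) of at least 10%.

Gene dependency uses the ratio $r = \mathrm{WT}/(\mathrm{p150KO}+1)$ of
mean per-condition gene scores (max peak fold per gene):
strong ($r \ge 4$), mild ($1 < r < 4$), independent ($r < 1$),
p150KO-specific (WT = 0, p150KO > 1), and dKO-specific
(WT = p150KO = 0, dKO > 1).

## Worked example

```r
library(editpeaks)

cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 30000,
                  n_genes = 6, n_peaks = 5, background_depth = 30)
res <- run_synthetic_pipeline(cfg)

res$peaks[["WT_rep1"]][, c("contig", "start0", "end0", "strand",
                           "mod_class", "fold_enrichment", "q_score")]
#>     contig start0  end0 strand mod_class fold_enrichment   q_score
#> 1 contig_1   3886  4329      +   inosine        9.979756  40.79778
#> 2 contig_1  15132 15523      -       m6a       11.923728 100.00000
#> 3 contig_1  20043 20435      +   inosine       11.193449  78.81929
#> 4 contig_1  23550 23857      -   inosine       14.197005  95.94542
#> 5 contig_1  26494 26810      +   inosine        8.226029  72.78639
```

The high-confidence wild-type peaks sit on the planted intervals, with
spike-scaled folds near the planted values (8–16 in this design). Inside
them, pileup calls recover the planted editing rates:

```r
head(res$sites[["WT_rep1"]][, c("pos0", "strand", "depth", "alt_count", "rate")], 3)
#>    pos0 strand depth alt_count      rate
#> 1  3988      +  3637       974 0.2678031
#> 2  4075      +  3588      2005 0.5588071
#> 3  4130      +  3577      2303 0.6438356
```

Across the three conditions (two replicates each), per-gene scores and
dependency categories, and the knockout reductions in inosine peak
counts:

```r
res$dependency[, c("gene_id", "wt_score", "p150ko_score", "ratio", "category")]
#>    gene_id  wt_score p150ko_score      ratio    category
#> 1 gene_001 10.902739     12.47431  0.8091504 independent
#> 2 gene_004 12.285108      5.95063  1.7674813        mild
#> 3 gene_005 14.400682      0.00000 14.4006815      strong
#> 4 gene_006  7.131255      0.00000  7.1312551      strong

res$reductions
#> p150KO    dKO
#>     50    100
```

All four genes match their planted categories (this design planted one
independent, one mild and two strong genes). `write_results(res, dir)`
writes per-sample BED6+3 peaks, VCF v4.2 + TSV editing sites, annotation
TSVs, the dependency table and a JSON summary — byte-identical across
reruns of the same seed.

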