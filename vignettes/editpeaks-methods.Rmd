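---
title: "Methods: peak calling, editing-site detection and isoform-dependency classification in editpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling, editing-site detection and isoform-dependency classification in editpeaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editpeaks)
```

This vignette explains the models and procedures implemented in
`editpeaks`, the assumptions behind them, the tunable parameters and
their defaults, and the design choices made where more than one
reasonable convention exists. It also describes what the synthetic-data
generator does and does not emulate, and therefore what a passing test
suite does and does not demonstrate about real data.

## 1. The assay and its data

Bead-enrichment modification sequencing captures RNA fragments that
carry a modification (here inosine or m6A) onto bead surfaces via
modification-specific binders; roughly 90% of fragments are captured and
the remaining solution fraction becomes a *solution control* library
prepared with analogous chemistry. During on-bead priming each molecule
receives a modification barcode (MBC) identifying the captured class and
a unique molecular identifier (UMI). Synthetic spike-in RNAs — some
modified, some not — are mixed in before capture, so the relative
recovery of modified versus unmodified spikes measures the capture
advantage of a modified molecule.

`editpeaks` consumes *mapped* reads. Alignment itself is out of scope:
reads arrive either as a documented TSV alignment table (one row per
mapped read: id, contig, 0-based start, strand, length, MBC class, UMI,
and observed base substitutions) or are constructed by the simulator in
the same form. All internal coordinates are 0-based half-open; BED and
VCF files on disk follow their own conventions.

## 2. Read processing

**Barcode extraction** (`extract_barcodes`) slices the configured MBC
and UMI off the read 5' end. The real assay's MBC length and code table
are unpublished, so both are configurable (`barcode_layout`); the
default is a 4-base MBC with two codes (inosine, m6A) and an 8-base UMI.
An MBC absent from the table maps to class `"unknown"` and is flagged
rather than dropped, so misassignment is visible downstream. Reads
shorter than MBC+UMI are rejected with reason `too_short_for_barcodes`.

**Quality filtering** (`filter_reads`) trims the 3' end at the first
4-base window whose mean Phred quality drops below Q20 (both window and
threshold configurable), then removes inserts shorter than 30 bases.
The 30-base cutoff is the assay's published filter; the window trim is
our concrete reading of "low-quality bases were trimmed out", chosen to
match common sliding-window trimmers.

**Deduplication** (`deduplicate`) collapses reads sharing
(MBC class, UMI, contig, strand, 5' start). The published description
keys on MBC and UMI only; we add the mapped position and strand because
8-base UMIs collide across loci at any realistic library size, and
positional keying is standard UMI practice. The survivor is the
lexicographically smallest read id, making the operation deterministic
and idempotent. No 1-mismatch UMI merging is attempted: exact-match
collapsing keeps the operation order-free and reproducible, at the cost
of slightly under-collapsing sequencing errors in UMIs.

## 3. Peak calling

### 3.1 Signal

Each modification class is treated as its own split library (reads are
split by MBC upstream), and every step below is strictly class-local:
one class's reads can never influence another class's peaks. For each
(contig, strand, class) the enrichment and control coverage tracks are
compared through

\[ x(p) = \log_2 \frac{e(p) + c_0}{s\,c(p) + c_0}, \]

smoothed by a centered moving average of width `smooth_window`
(truncated at contig ends so the signal is defined everywhere). The
pseudocount `c0 = 1` read regularizes zero-control positions — control
gaps are never excluded, only damped. The library-size factor `s` is the
ratio of genome-wide **median** depths between the class's enrichment
and control tracks. Medians rather than totals matter here: the
enrichment library concentrates a large fraction of its reads into the
enriched minority of the genome, so a total-count ratio would scale the
control up and bias every fold estimate downward; the median tracks the
background level on both sides.

### 3.2 Summits, boundaries, merging

Candidate summits are local maxima of the smoothed signal (plateaus
collapse to their middle position) with topographic prominence of at
least `min_prominence` (default 1, i.e. two-fold in log2 units):
prominence is the summit height above the higher of the two saddles
separating it from higher terrain, the same definition scientific
signal-processing libraries use. Each accepted summit extends to where
the smoothed signal falls below (summit − prominence/2) or below zero;
overlapping candidate intervals merge, the merged summit being the
highest point. Peaks narrower than `min_width` (default 30 bases) are
discarded.

### 3.3 Fold enrichment

A peak's raw fold is its maximal smoothed enrichment depth (plus
pseudocount) over the library-scaled mean control depth across the peak
(plus pseudocount). Whether published folds are summit-based or
mean-based is not stated anywhere we could check; we evaluated both and
chose this hybrid deliberately. A pure summit-based ratio divides two
single-position estimates, and because coverage is correlated over a
fragment length, the control trough under a summit is effectively a
single noisy draw — at background depth 20–30 this puts ±30–40% noise on
every fold and that noise propagates straight into the dependency
ratios. Averaging the control over the whole peak pools tens of
fragments and stabilizes the denominator, while the numerator (smoothed
summit depth of a genuine peak) is relatively deep and quiet. On clean
rectangular signal the two definitions agree.

Raw folds are divided by the spike-in enrichment factor
(`spike_enrichment_factor`, the ratio of modified to unmodified
recovery ratios) to give the final fold enrichment. Scaling applies to
folds only, never to boundaries.

### 3.4 Confidence scores

The high-confidence classifier of the original pipeline is a proprietary
ensemble (hidden Markov plus random forest) whose features and training
data are unpublished; this package implements the reproducible part of
that contract — an HMM posterior expressed as a PHRED q-score — and
omits the random-forest component deliberately. This is a
faithful-contract reimplementation, not a byte-identical one.

The smoothed signal is averaged in consecutive bins of `smooth_window`
bases and a two-state (background/enriched) Gaussian HMM is fitted by
EM. Numerical choices, all deterministic:

* initialization splits the observations at their median, seeding the
  two states' means and standard deviations from the halves; transitions
  start sticky (0.95);
* at most 100 iterations, stopping when the log-likelihood improves by
  less than 1e-6; standard deviations floored at 1e-4;
* the higher-mean (enriched) state is constrained during fitting to be
  at least as dispersed as the background state. Without this, EM can
  converge to a thin high state whose own far tail is likelihood-
  assigned back to the *background* component, so the strongest true
  peaks would be scored as background — a known pathology of
  unconstrained two-Gaussian fits, cured by this one-line constraint;
* a signal with numerically zero variance cannot support two states;
  the fit is flagged degenerate and posteriors default to 0.5
  (q ≈ 3.01), which correctly conveys "no information".

When the pipeline processes several samples together
(`run_pipeline`), one HMM per modification class is fitted on the bins
pooled across *all* samples' tracks of that class. This anchoring is the
key to sensible knockout behavior: in a p150/p110 double-knockout the
inosine tracks are pure background, and a per-track fit would split that
noise into two states and grade noise bumps as confidently "enriched";
pooled across samples, the enriched state sits where the wild-type peaks
are and knockout noise scores near zero. Because pooling is per class,
m6A scoring is unaffected by inosine reads — removing every inosine read
from an experiment leaves the m6A peak set byte-identical.

A peak's q-score is `-10*log10(max(1e-10, 1 - posterior))`, capped at
100, where the posterior is the mean enriched-state posterior over the
peak's bins, weighted by each bin's base overlap with the peak (an edge
bin that touches the peak by one base should not dilute the score).

High confidence requires `q >= q_min` and enrichment depth
`>= depth_min` at the peak maximum. `depth_min = 5` is the published
requirement. The q cutoff is not published; the default 13 corresponds
to posterior ≈ 0.95 and is configurable.

### 3.5 Parameter summary

| parameter | default | units | role |
|---|---|---|---|
| `smooth_window` | 25 | bases | moving-average width and HMM bin size |
| `pseudocount` | 1 | reads | regularizes the log-ratio |
| `min_prominence` | 1 | log2 units | minimum summit prominence (2-fold) |
| `min_width` | 30 | bases | minimum peak width |
| `q_min` | 13 | PHRED | high-confidence posterior cutoff (≈0.95) |
| `depth_min` | 5 | reads | high-confidence enrichment depth |

## 4. Editing sites

`pileup` counts bases per column from the alignment table, split by read
strand, with reference bases taken from the genome and per-read
substitutions applied from the table's override field; column depth is
capped at 20000 reads (the cap of the variant caller the assay's
publication used), counting the first 20000 covering reads in
deterministic (start, read id) order.

`call_editing_sites` reports a column iff all four clauses hold:

1. the position lies inside a high-confidence *inosine* peak;
2. the reference base matches the peak's gene-strand context — A with
   G alternates on a plus-strand peak, T with C alternates (the
   reference-forward image of A→G) on a minus-strand peak;
3. column depth is strictly greater than 5 (the published filter is a
   strict inequality);
4. the variant rate is at least 10%.

Two conventions were open and are fixed as follows. *Variant rate* is
alternate reads over total column depth (the allele-fraction convention
of standard callers' FORMAT fields), not alt/(ref+alt); and both read
strands are counted jointly at a site, since nothing in the assay makes
the edited base strand-limited on the sequencing side. Base-quality
recalibration (BAQ) is an alignment-quality adjustment belonging to the
external caller and is omitted. Sites on a peak boundary follow the
half-open rule: start inclusive, end exclusive. Multi-allelic columns
contribute only their A→G (or T→C) component.

`editing_density` is `100 * n_sites / peak_width`, the sites-per-100-bp
summary used to characterize editing within peaks.

On disk, sites are written as VCF v4.2 (1-based positions, REF/ALT A/G
or T/C, INFO: peak id, strand, edit rate; FORMAT: DP and AD) plus a TSV
mirror. The writer emits the small fixed schema directly so that output
is byte-stable.

## 5. Annotation

`build_feature_index` digests a GTF-style annotation into intervals
classed exon, intron, 5'/3' UTR and lncRNA: introns are the exact gaps
between a transcript's consecutive exons; UTRs are exon-minus-CDS
pieces, sided by strand relative to the CDS span; exonic intervals of
lncRNA-biotype genes carry class `lncRNA`; for coding transcripts the
CDS carries the `exon` class (coding classes take precedence over the
generic exon where a CDS exists). Transcripts with overlapping exons are
rejected by name.

`annotate_peak` reports every (gene, class) pair overlapping a peak by
at least one base on the same strand; one base suffices because no
fractional threshold is published. Gene-level class assignment is the
union over isoforms — a peak intronic in one isoform and exonic in
another reports both. `region_distribution` counts distinct genes per
class; a gene modified in several regions counts once per region, so
class counts may sum to more than the number of genes (this matches how
the source experiment reports its 870-gene regional breakdown; those
published counts depend on the human annotation and deposited reads and
are not reproducible at desk scale, so they are not test targets).

## 6. Dependency classification

Per sample, a gene's score is the **maximum** fold enrichment over its
annotated inosine peaks — robust to one peak fragmenting into two —
and condition scores are arithmetic means over replicates (how the
published per-gene ratios combined two replicates is unstated; the mean
is the obvious symmetric choice). Classification applies, in order:

1. WT = 0, p150KO = 0, dKO > 1 → `dko_specific`
2. WT = 0, p150KO > 1 → `p150KO_specific`
3. r = WT/(p150KO+1) ≥ 4 → `strong`
4. 1 < r < 4 → `mild`
5. r < 1 → `independent`
6. otherwise `unclassified`

A ratio of exactly 1 falls in none of the published intervals and is
deliberately left `unclassified` rather than silently binned.

`reduction_summary` reports percent reductions of inosine peak counts
relative to wild type. When a knockout has the same number of replicates
as the reference, counts are rank-paired (both sorted decreasingly,
pairing clone-wise) and per-pair reductions `1 - KO/WT` are averaged;
this is the convention that reproduces per-clone reporting — on the
published counts it yields 73.4% (p150 KO) and 99.9% (double KO) —
while remaining invariant to the order in which replicates are listed.
With unequal replicate numbers it falls back to the ratio of mean
counts. Results are rounded to one decimal, the published precision.

`cluster_gene_scores` z-scores each gene across samples (zero-variance
genes get z = 0), aggregates to condition means, and clusters with
Euclidean distance and Ward linkage (`hclust(method = "ward.D2")`,
the agglomerative scheme matching sklearn's ward/euclidean setting),
cut to the requested number of clusters.

## 7. The synthetic-data generator

`simulate_reference` builds random contigs and spliced genes
(configurable exon/intron/UTR length ranges; a fraction of genes are
single-biotype lncRNAs; spike-ins are separate 200-base contigs, never
overlapping the genome). `simulate_experiment` plants:

* **peaks**: intervals inside genes, class inosine or m6A, fold drawn
  from `fold_enrichment_range`;
* **editing sites**: gene-strand adenosines inside inosine peaks, rates
  drawn from a Beta(2, 4) distribution (right-skewed, mean 1/3 — a
  realistic shape for editing stoichiometries);
* **dependency categories** per inosine-peaked gene, with per-condition
  intensity scalings (defaults: strong KO=0, mild KO=0.4, independent
  KO=1, p150KO-specific WT=0; the double knockout scales everything to
  0; m6A peaks scale 1 everywhere, mirroring their observed stability
  across knockouts). Planting weights are 50/20/20/10%, roughly the mix
  the source experiment observed;
* **reads**: fixed-length (100 nt) single-end fragments; each
  (class, strand) track receives Poisson background at
  `background_depth` reads/base in both libraries, and peaks add
  enrichment-library reads with uniformly distributed starts across the
  fragment-extended interval, giving flat expected coverage over the
  peak. Reads covering a planted site carry the edited base with
  probability equal to the site's per-condition realized rate (the
  planted rate times the gene's condition scaling — editing disappears
  with the enzyme);
* **spike counts**: Poisson around a base count of 1000 (control) and
  base × true recovery (enriched); defaults are two modified spikes at
  10× recovery and two unmodified at 1×.

Planted folds are expressed in **spike-calibrated units**: the raw
coverage enrichment planted on the genome is `1 + (fold − 1)·φ`, where
φ is the true modified/unmodified recovery ratio implied by the spike
set. Dividing the called raw fold by the measured spike factor (≈ φ)
then recovers the planted value, so the simulator exercises the entire
calibration loop and a planted fold of 1 still means a null track. The
recovered fold is `fold − 1 + 1/φ`, a small known shift at φ = 10.

Recovery of planted peaks is judged against the peak's **enrichment
footprint** (`signal_start0/signal_end0`: the capture interval extended
by read length − 1 per side), because fragments carrying any peak base
necessarily pile coverage there — an ideal coverage-level caller reports
the footprint, not the capture core, and for peaks narrower than about
two fragment lengths the distinction decides the overlap metric.

All randomness flows from the single `seed` through fixed per-stage
offsets, and the caller's RNG state is saved and restored, so identical
configurations give byte-identical outputs (the test suite and the
acceptance script verify this on the written BED/VCF/TSV/JSON files).
All internal orderings use locale-independent sorting, so results do not
depend on the environment's collation settings.

**What the generator does not emulate** — and therefore what passing
tests cannot show about real data: sequencing errors beyond the planted
substitutions (a uniform error rate is available but defaults to 0),
indels, paired-end fragments, variable fragment lengths, transcript
expression gradients, rRNA contamination, repeat-driven multi-mapping
(Alu elements, the dominant real substrate context, do not exist in the
random genomes), PCR-duplicate structure (deduplication is exercised by
construction in unit tests instead), and germline A/G polymorphisms
masquerading as edits. Results on real libraries additionally depend on
the upstream aligner, which is out of scope by design.

## 8. Problem sizes used by the tests

The test suite and the acceptance script run complete three-condition
experiments (two replicates per condition) on a single 30-kb contig with
6 genes and 5 planted peaks at background depth 30, wild-type-only
recovery runs on 20-kb contigs, false-peak counts on one hundred 100-kb
null tracks, and editing-rate recovery at ~1000× site depth. These sizes
were chosen to give every stage enough statistical room for its stated
tolerance (e.g., binomial noise at depth 1000 bounds the achievable rate
error near 0.013) while keeping full runs fast enough to repeat across
many seeds.

## 9. Known limitations

* The HMM scorer needs at least one genuinely enriched region somewhere
  in the pooled class bins to anchor its enriched state; an experiment
  that is entirely null for a class degrades to prominence-and-depth
  filtering only.
* Dependency categories whose ratio sits near a published boundary
  (especially independent, r < 1, versus mild) are intrinsically noisy:
  with two replicates and realistic depths, roughly one borderline gene
  in twenty lands on the wrong side. This is a property of the ratio
  scheme, not of the implementation.
* Fold estimates inherit a small downward shift (`1/φ − 1` in
  calibrated units) from pseudocounting, visible only at very low folds.
* The feature index assumes one transcript per gene suffices for intron
  derivation per isoform; overlapping genes on the same strand report
  all matches rather than choosing a winner.
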