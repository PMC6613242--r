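---
title: "Methods: from contact maps and SNP panels to variant-gene links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from contact maps and SNP panels to variant-gene links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculink)
```

`vasculink` models the integrative analysis of an inflamed endothelial
cell system: resting (NT) cells against TNF-α stimulation at 4 and 24
hours, profiled by RNA-seq, ATAC-seq and in situ Hi-C, and intersected
with GWAS panels for coronary artery disease (CAD), blood pressure (BP)
and — as a non-vascular control — body mass index (BMI). This vignette
explains each model, the tunable parameters and their defaults, what the
synthetic genomes emulate (and deliberately do not), and the numerical
choices made where the methods literature leaves room.

## Coordinates and containers

All intervals are 0-based half-open (BED convention) everywhere inside
the package; 1-based dialects are converted at reader boundaries.
Overlap therefore requires at least one shared base: `[0,100)` and
`[100,150)` abut but do not overlap, and a SNP at a peak's `end`
coordinate is outside the peak. Interval arithmetic is delegated to
GenomicRanges/IRanges behind this convention. Contact matrices are held
dense per chromosome with a sparse COO text interchange format — the
package targets desk-scale synthetic genomes and modest real extracts,
not whole-genome `.hic` stores.

## Differential classification

Counts are normalised by median-of-ratios size factors: the factor for a
sample is the median over features (with nonzero geometric mean) of
`count / geometric mean of the feature`. Fold-change is
`log10((m2 + 0.5) / (m1 + 0.5))` on normalised condition means; the 0.5
pseudocount keeps zero-count features finite and is configurable. The
per-feature test is a two-sided Welch t-test on `log2(normalised + 0.5)`
replicate values, adjusted by Benjamini–Hochberg within each comparison.
A feature is classified `up` when FDR < 0.001 **and** log₁₀FC > 0.3,
`down` symmetrically — both inequalities strict — and the study-level
differential set is the union over the three condition comparisons.

The negative-binomial Wald machinery of DESeq2 is deliberately **not**
reimplemented: downstream stages consume the classified feature sets,
and the classification layer (thresholds, BH, three-way union) is what
this package owns. The table format accepts externally computed
fold-changes and p-values, so real DESeq2 output can be dropped in. One
consequence matters for the synthetic study design: a per-feature t-test
shares no dispersion information across features, and with two or three
replicates its Welch degrees of freedom can fall to ~2, where no effect
size can reach FDR < 10⁻³. The generator therefore defaults to four
replicates per condition with tight cell-line-like dispersion (0.005)
and a large planted effect (|log₁₀FC| = 0.5, a ~3.2-fold change), where
the classifier's recall is ~0.9–1.0. This is a property of the t-test
substitute, not of the thresholds.

## Knight–Ruiz balancing

`kr_balance()` implements the Knight–Ruiz inner–outer Newton iteration
(conjugate-gradient inner solves) for symmetric matrix balancing: it
finds per-bin weights `w` with `diag(w) A diag(w) e = e`, i.e. every
unmasked row of the balanced matrix sums to 1 within the requested
tolerance (default 10⁻⁶ on the residual; the acceptance checks use
10⁻⁵ relative on row sums). For positive symmetric input the balanced
matrix is unique, so the tests verify KR against an independent Sinkhorn
fixed-point iteration run to 10⁻¹². Balancing is scale-invariant
(`c·A` yields `w/√c` and the same balanced matrix), masked bins are
carried through untouched, and a structurally unbalanceable matrix (an
unmasked all-zero row) is an error that asks for a wider mask rather
than a silent fix.

Masking: matrices loaded from COO text mask zero-marginal bins plus bins
below the 2nd percentile of nonzero marginals, mirroring common Hi-C
practice for sparse-bin exclusion (the upstream pipelines do not publish
their exact rule, so the percentile is configurable). Simulated matrices
mask only truly empty bins — the simulation has no coverage bias, and a
quantile rule would systematically mask boundary-adjacent bins whose
marginals are genuinely depressed by domain structure.

## A/B compartments

PCA directly on balanced contacts recovers distance decay, not
compartments, so `call_compartments()` follows the eigenvector route:
balanced matrix → observed/expected (each entry divided by its diagonal
mean) → Pearson correlation matrix → first principal component. The PC1
sign is arbitrary, so it is flipped when negatively correlated with a
gene-density track; bins with PC1 > 0 are labelled A, < 0 B. Exact zeros
(which arise only in degenerate inputs) inherit the previous unmasked
label to preserve contiguity, with leading ties masked. Chromosomes with
fewer than 20 usable bins are not called. Between conditions, switching
is read bin-wise from the labels, contiguous switched bins are merged to
intervals, and the switched fraction is taken over bins called in both
conditions.

Class enrichment in switching compartments assigns features to switch
intervals by **midpoint** containment (the unambiguous choice when a
feature straddles a boundary), compares the in-switch class fraction
`p̂` with the background fraction `p₀`, reports `p̂/p₀`, and computes a
one-sided exact binomial tail in the direction of the observed
enrichment (sidedness configurable). With no in-switch features, or an
empty background class, the result is flagged undefined rather than
raised as an error.

## TADs from insulation scores

At 10-kb resolution, the insulation score of bin *i* is the mean
balanced contact in the square `[i−w, i−1] × [i+1, i+w]` with
`w = 500 kb / bin size` ("mean" mode); bins whose square leaves the
chromosome, sits on a masked bin, or is more than half masked carry no
score. Scores are normalised as log₂ of score over the chromosome mean.
The delta vector at bin *i* is the mean normalised insulation over the
200-kb window right of *i* minus the window left of it; insulation
minima are delta's −→+ zero crossings. Boundary strength is the swing of
delta across the crossing (nearest local maximum right of it minus
nearest local minimum left of it), kept when strictly above the 0.1
noise threshold, and the boundary bin is the insulation minimum between
those two extrema — placing the boundary at the crossing bin itself
lags the minimum when the profile is asymmetric. Candidates within 3
bins of a masked bin are dropped (the margin-of-error parameter applied
as a masked-proximity filter). TADs are the intervals between
consecutive kept boundaries; segments before the first and after the
last boundary are chromosome-end regions and excluded, as are TADs
overlapping supplied excluded regions (e.g. centromeres).

Boundary stability between conditions matches boundaries within a 20-kb
buffer (inclusive). Feature metaprofiles extend each TAD by 35 kb on
both sides before mapping to 100 relative bins, so boundaries land at
fixed relative positions despite TADs differing in size; profiles are
densities per kb averaged over TADs. The SNP boundary-distance test
extends boundaries by a 10-kb outward buffer (distance 0 inside it) and
compares the trait median distance against 100 matched control sets with
the pseudo-counted empirical P `(r+1)/(n+1)`, which can never reach 0.
SNPsnap itself is not called: an internal matcher samples controls,
without replacement within each set, that agree with each trait SNP on
MAF (±0.05 absolute) and on gene density, distance to nearest gene and
proxy count (±50% relative), doubling the tolerances stepwise (with a
message) for trait SNPs without candidates. A capacity check requires
the pool to hold at least `n_sets × set size` candidates.

## SNP enrichment in open chromatin

LD expansion keeps sentinels and proxies with r² strictly above 0.8 and
collapses duplicate positions. The per-library statistic is the fraction
of peaks containing at least one SNP — counting peaks, not SNPs, makes
libraries with different peak counts comparable and keeps a peak with
three proxies from counting three times. Significance uses a
circular-shift null: each chromosome's SNP set is shifted by one uniform
random offset (mod chromosome length) per shift, so LD clusters move
rigidly and the set's internal spacing is exactly preserved — the
clumping that breaks naive binomial nulls is retained. The empirical P
is again `(r+1)/(n+1)`. Because the overlap count is integer-valued,
rank ties make the test mildly conservative when the count has few
attainable values; the calibration study in the acceptance tests
therefore uses panels (600 SNPs, ~14% peak coverage) where the null
count is spread over enough values that the size stays within
[0.03, 0.07] at α = 0.05. The genome-wide enrichment tool cited by the
original analysis is not re-derived; the circular shift is this
package's documented, fully specified replacement, and the matched-SNP
machinery offers an alternative null.

## Variant-to-gene linking

Loop support is computed directly from the raw contact matrix: the sum
of counts over bin pairs covered by the two anchors, each padded by 5 kb
(configurable). If padding makes the anchors share a bin the support
would mix self-proximity signal with loop signal, so the candidate is
dropped with a log message. This replaces a read-level loop caller with
the reproducible matrix-level quantity behind the same ≥ 20-read
criterion; externally called loops can be supplied by writing their
support into the record directly. Promoter anchors default to ±500 bp
around the TSS when only a TSS is given. The cascade keeps a
(SNP ∈ peak, gene) candidate when support ≥ 20, the gene is expressed
above the bottom 10 percentile (percentiles computed among expressed
genes; "not expressed" and "bottom decile" are two sequential
exclusions), and the SNP–gene eQTL P < 10⁻³ — a pure conjunction, so
filter order cannot change the passing set. The stringent tier
additionally requires a differential peak, a differential gene and
eQTL P < 10⁻⁵. Summaries report combination counts, distinct sentinel
loci per trait, and the mean ± population SD of peak-to-promoter
midpoint distances.

## The synthetic genomes

One simulated chromosome (default 10 Mb) carries a full architecture:

* **Compartment blocks** alternate A/B on the 50-kb bin grid with
  exponential lengths (mean 1.2 Mb, floor one TAD). The expected contact
  between bins *i,j* is `d(|i−j|) × plaid × tad × loop` with distance
  decay `d(s) = 1/(1+s)`, plaid factor `1±a` (amplitude 0.4 by default),
  same-TAD factor `1+t` (t = 1, i.e. 2× contrast), and a multiplicative
  focal enrichment (default 10×) at planted loop anchors. Counts are
  Poisson draws scaled to a total depth of 10⁶ per matrix; replicates
  share the expected matrix and differ only in noise.
* **Compartment edges coincide with TAD boundaries**, as A/B transitions
  do in real genomes. This is not merely cosmetic: an independently
  planted compartment edge creates a genuine insulation minimum that is
  not a planted TAD boundary, which would make boundary "precision"
  unmeasurable. Likewise the minimum TAD size (550 kb) exceeds the
  500-kb insulation square, because the method cannot resolve domains
  smaller than its window — small planted TADs would shift the apparent
  minima of their neighbours.
* **Switching** flips the A/B sign of a contiguous run of compartment
  bins totalling 2.1% of the chromosome in the stimulated conditions,
  and 7.7% of internal TAD boundaries are absent from them (adjacent
  domains merge). On a 200-bin chromosome these planted fractions are
  quantized, which is why recovered values read 2.0% and ~8–9%.
* **Counts** are negative-binomial with per-sample library factors in
  [0.7, 1.3]; 10% of features receive a planted log₁₀ fold-change of
  magnitude 0.5 with an early/late/sustained response pattern.
* **SNP panels** place 50 sentinels per trait, 30% of CAD/BP sentinels
  inside peaks (BMI stays unenriched as the negative control), LD
  proxies at exponential distances (mean 50 kb) with
  `r² = exp(−d / 50 kb)`, and attribute columns (MAF, gene density,
  gene proximity, proxy count) for matching, plus a large background
  pool. For each planted loop, a peak with a disease sentinel is placed
  on one anchor and a well-expressed gene promoter on the other, with a
  strong eQTL entry — the ground truth for link recall. eQTL decoys get
  uniform P values.

What the generator does **not** emulate: sequence content, mappability
and coverage bias, trans-chromosomal contacts, realistic karyotypes,
full LD matrices (only pairwise r² to the sentinel is consumed), and
expression–architecture coupling (planted fold-changes are independent
of compartment switching, so switching enrichments are null on
synthetic data — the enrichment arithmetic is validated against the
reported class fractions instead). Passing recovery tests therefore
demonstrates correctness of the callers under planted structure, not
performance on real libraries.

## Determinism and problem sizes

Every stochastic step derives its seed from the run seed keyed by a
stage name (`derive_seed`), so adding a stage never perturbs another's
draws, and `run_pipeline()` is byte-reproducible for a fixed
configuration. The shipped study sizes — 200 compartment bins, 600–1000
TAD bins, 400–800 features, panels of tens of sentinels, 100 matched
sets, 200–1000 shifts — keep a full pipeline run under ~10 seconds and
the complete test suite under two minutes while leaving every statistic
estimable; all sizes scale up through `sim_config()`.

## Known limitations

The Welch substitute needs more replicates than a shared-dispersion
model, as discussed above. KR is implemented for dense per-chromosome
matrices and has no sparse path. The boundary-distance and metaprofile
utilities are single-chromosome (SNPs on chromosomes without boundaries
are excluded with a message). The circular-shift null is mildly
conservative for very small panels. Percentile and eQTL thresholds are
strict inequalities throughout; datasets whose published results used
non-strict cutoffs should adjust the thresholds, all of which live in
`run_config()`.
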