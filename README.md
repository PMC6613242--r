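# vasculink

Connecting GWAS variants for vascular disease to their candidate target
genes through the regulatory genome of activated endothelial cells.

Genome-wide association studies place most variants for coronary artery
disease (CAD) and blood pressure (BP) in non-coding DNA, where their
effects run through regulatory elements rather than protein sequence.
`vasculink` implements, as a tested and reusable R pipeline, the
integrative analysis used to interpret such variants in a TNF-α-stimulated
endothelial cell system:

* **Differential classification** of genes (RNA-seq) and open-chromatin
  peaks (ATAC-seq): a feature is called up/down (or opened/closed) when
  its Benjamini–Hochberg FDR < 0.1% *and* |log₁₀ fold-change| > 0.3 in any
  of the three condition comparisons (NT vs 4 h, NT vs 24 h, 4 h vs 24 h).
* **Knight–Ruiz (KR) matrix balancing** of Hi-C contact maps: per-bin
  weights *w* such that the balanced matrix *b₍ᵢⱼ₎ = wᵢ·rawᵢⱼ·wⱼ* has
  equal (unit) row sums, removing bin-wise coverage bias.
* **A/B compartments**: per chromosome, the balanced matrix is transformed
  to observed/expected by diagonal, converted to its Pearson correlation
  matrix, and PC1 of that matrix — sign-oriented so positive values track
  gene-rich bins — partitions the genome into active (A, PC1 > 0) and
  repressed (B, PC1 < 0) compartments. Condition switching (A↔B) is read
  bin-wise, and class enrichments in switching compartments are scored
  with an exact one-sided binomial test.
* **TAD calling by insulation score** (Crane-style): each 10-kb bin's
  score is the mean balanced contact in a 500-kb square across it; TAD
  boundaries are insulation minima located by the zero crossings of a
  200-kb delta vector, kept when their strength exceeds the 0.1 noise
  threshold. Boundary stability between conditions uses a 20-kb buffer.
* **SNP enrichment in open chromatin**: sentinel GWAS SNPs are expanded
  with LD proxies (r² > 0.8), the fraction of peaks containing a SNP is
  reported per library, and significance comes from a circular-shift null
  that moves each chromosome's SNP set rigidly, preserving LD clumping.
  A SNPsnap-style matcher (MAF, gene density, gene proximity, proxy
  count) supplies matched control SNP sets for the TAD-boundary distance
  test with empirical P = (r+1)/(n+1).
* **Variant-to-gene linking**: candidate (SNP ∈ peak) × (promoter)
  combinations are kept when the Hi-C loop support is ≥ 20 reads, the
  gene is expressed above the bottom 10 percentile, and the SNP is an
  eQTL for the gene (P < 10⁻³; stringent tier additionally requires
  differential peak and gene and P < 10⁻⁵).

Real inputs at the scale of the original study (deposited Hi-C, RNA-seq,
ATAC-seq, GTEx, 1000 Genomes) are not shipped; instead a first-class
**synthetic-data module** generates every pipeline input with planted
ground truth — plaid compartment structure, block-diagonal TADs with
focal loops, negative-binomial counts with planted log₁₀ fold-changes,
and sentinel/proxy SNP panels with decaying r² — so that every caller can
be scored for recovery without downloads.

## Worked example

```r
library(vasculink)
cfg <- run_config(sim = sim_config(seed = 42))   # all thresholds at their study defaults
res <- run_pipeline("out", cfg)

sw <- res$compartments$switches
cat(sprintf("PC1 correlation NT vs T4: %.3f\n", sw$pc1_correlation))
cat(sprintf("genome switched: %.1f%%\n", 100 * sw$genome_fraction_switched))
cat(sprintf("TAD boundaries (NT): %d; changed on stimulation: %.1f%%\n",
            nrow(res$tads$tads$NT$boundaries),
            100 * res$tads$stability$changed_fraction))
print(res$enrich[, c("trait", "fraction", "observed", "null_mean", "empirical_p")],
      row.names = FALSE)
s <- res$link$summary
cat(sprintf("passing links: %d (%d CAD / %d BP loci), mean distance %.0f kb\n",
            s$n_combinations, s$loci_per_trait["CAD"], s$loci_per_trait["BP"],
            s$distance_mean_bp / 1000))
cat(sprintf("differential genes (any comparison): %d\n",
            length(res$differential$genes$union$features)))
```

The run simulates one synthetic chromosome (10 Mb) in three conditions,
then executes differential → balance → compartments → tads → enrich →
link, writing plain-text artifacts plus a manifest to `out/`. The summary
lines above print:

```
PC1 correlation NT vs T4: 0.965
genome switched: 2.0%
TAD boundaries (NT): 11; changed on stimulation: 9.1%
 trait   fraction observed null_mean empirical_p
   CAD 0.03590426       28    10.376 0.000999001
    BP 0.04654255       40    11.574 0.000999001
   BMI 0.01329787       11     9.254 0.330669331
passing links: 40 (6 CAD / 8 BP loci), mean distance 212 kb
differential genes (any comparison): 38
```

Reading this: compartments are nearly identical between resting and
stimulated cells except the planted 2% switched region; ~9% of TAD
boundaries change (one merged domain); CAD and BP SNPs sit in
open-chromatin peaks far above the circular-shift null (empirical
P ≈ 10⁻³, the minimum attainable with 1000 shifts) while the BMI control
panel does not; and the linking cascade recovers the planted
SNP–peak–gene combinations at enhancer–promoter distances of a couple of
hundred kb.

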