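#' Expand sentinel SNPs with their LD proxies
#'
#' Sentinels are always included; a proxy is included iff its r-squared to
#' the sentinel strictly exceeds the threshold (the r2 > 0.8 rule).
#' Duplicate positions are collapsed.
#'
#' @param panel SNP panel data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `type` (`sentinel`/`proxy`), `sentinel_id`, `r2`, `trait`.
#' @param r2_threshold strict lower bound on proxy r-squared (default 0.8).
#' @param trait optional trait to restrict to.
#' @return data.frame of qualifying SNP positions (`snp_id`, `chrom`,
#'   `pos`, `sentinel_id`, `trait`), one row per distinct position.
#' @export
expand_ld <- function(panel, r2_threshold = 0.8, trait = NULL) {
  if (!is.null(trait)) panel <- panel[panel$trait %in% trait, , drop = FALSE]
  keep <- panel$type == "sentinel" | panel$r2 > r2_threshold
  out <- panel[keep, c("snp_id", "chrom", "pos", "sentinel_id", "trait"), drop = FALSE]
  out <- out[!duplicated(out[, c("chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of peaks containing at least one SNP
#'
#' A peak counts once if it contains one or more SNP positions under
#' half-open containment, whatever the number of SNPs inside; reporting a
#' fraction of peaks keeps libraries with different peak counts
#' comparable.
#'
#' @param peaks [genomic_intervals()] (must be non-empty).
#' @param snps data.frame of SNP positions (`chrom`, `pos`, 0-based).
#' @return list with `n_peaks`, `n_peaks_with_snp`, `fraction`.
#' @export
peak_snp_fraction <- function(peaks, snps) {
  if (nrow(peaks) == 0) stop("zero peaks: fraction undefined")
  pts <- genomic_intervals(snps$chrom, snps$pos, snps$pos + 1)
  hits <- intersect_intervals(pts, peaks)
  k <- length(unique(hits$b_idx))
  list(n_peaks = nrow(peaks), n_peaks_with_snp = k, fraction = k / nrow(peaks))
}

#' Circular-shift enrichment test of SNPs in peaks
#'
#' The observed statistic is the number of SNP positions falling inside a
#' peak.  The null is built by circularly shifting the whole SNP position
#' set by one uniform random offset per chromosome (so LD clusters move
#' rigidly and their internal spacing is preserved, retaining the
#' clumping that confounds naive binomial tests) and recounting.  The
#' empirical P value is `(#{null >= observed} + 1) / (n_shifts + 1)`.
#'
#' @param peaks [genomic_intervals()].
#' @param snps data.frame of SNP positions (`chrom`, `pos`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_shifts number of circular shifts (default 1000).
#' @param seed optional integer seed.
#' @return list with `observed`, `null_counts`, `null_mean`, `null_sd`,
#'   `empirical_p`.
#' @export
enrichment_significance <- function(peaks, snps, chrom_lengths,
                                    n_shifts = 1000, seed = NULL) {
  stopifnot(all(snps$chrom %in% names(chrom_lengths)))
  merged <- merge_intervals(peaks)
  count_in_peaks <- function(chrom, pos) {
    total <- 0L
    for (ch in unique(chrom)) {
      iv <- merged[merged$chrom == ch, , drop = FALSE]
      if (nrow(iv) == 0) next
      p <- pos[chrom == ch]
      idx <- findInterval(p, iv$start)
      total <- total + sum(idx > 0 & p < iv$end[pmax(idx, 1)])
    }
    total
  }
  observed <- count_in_peaks(snps$chrom, snps$pos)
  null_counts <- with_seed(seed, {
    counts <- rep(0L, n_shifts)
    for (ch in unique(snps$chrom)) {
      L <- chrom_lengths[[ch]]
      p <- snps$pos[snps$chrom == ch]
      iv <- merged[merged$chrom == ch, , drop = FALSE]
      offsets <- floor(runif(n_shifts) * L)
      if (nrow(iv) == 0) next
      shifted <- outer(p, offsets, `+`) %% L # snps x shifts
      idx <- findInterval(shifted, iv$start)
      inpk <- idx > 0 & shifted < iv$end[pmax(idx, 1)]
      counts <- counts + colSums(matrix(inpk, nrow = length(p)))
    }
    counts
  })
  list(observed = observed, null_counts = null_counts,
       null_mean = mean(null_counts), null_sd = sd(null_counts),
       empirical_p = (sum(null_counts >= observed) + 1) / (n_shifts + 1))
}

#' SNPs overlapping transcription-factor motif hits
#'
#' Containment join between SNP positions and motif-hit intervals; one row
#' per (SNP, motif hit) combination.
#'
#' @param snps data.frame of SNP positions (`snp_id`, `chrom`, `pos`).
#' @param motif_hits [genomic_intervals()] with motif labels in `id`.
#' @return data.frame with `snp_id`, `motif`, `motif_idx`, `chrom`, `pos`.
#' @export
motif_snp_overlap <- function(snps, motif_hits) {
  if (nrow(motif_hits) == 0 || nrow(snps) == 0) {
    return(data.frame(snp_id = character(), motif = character(),
                      motif_idx = integer(), chrom = character(),
                      pos = numeric(), stringsAsFactors = FALSE))
  }
  pts <- genomic_intervals(snps$chrom, snps$pos, snps$pos + 1)
  hits <- intersect_intervals(pts, motif_hits)
  data.frame(snp_id = snps$snp_id[hits$a_idx],
             motif = motif_hits$id[hits$b_idx],
             motif_idx = hits$b_idx,
             chrom = snps$chrom[hits$a_idx],
             pos = snps$pos[hits$a_idx],
             stringsAsFactors = FALSE)
}
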