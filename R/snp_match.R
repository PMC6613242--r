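#' Draw matched control SNP sets
#'
#' For each trait SNP, control SNPs are sampled from a candidate pool
#' matched on minor allele frequency (absolute tolerance), gene density,
#' distance to the nearest gene and number of LD proxies (relative
#' tolerances), emulating SNPsnap-style matching with documented,
#' configurable tolerances.  Controls are sampled without replacement
#' within each set; when a trait SNP has no eligible candidate the
#' tolerances are widened stepwise (doubled) with a message, and matching
#' fails only when the pool is exhausted.
#'
#' @param trait_snps data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `maf`, `gene_density`, `dist_nearest_gene`, `n_proxies`.
#' @param pool candidate data.frame with the same columns, disjoint from
#'   the trait SNPs.
#' @param n_sets number of control sets (default 100).
#' @param maf_tol absolute MAF tolerance (default 0.05).
#' @param rel_tol relative tolerance on the other three attributes
#'   (default 0.5, i.e. +/- 50%).
#' @param seed optional integer seed for reproducible draws.
#' @return list of `n_sets` data.frames, each with one matched control row
#'   per trait SNP.
#' @export
match_snps <- function(trait_snps, pool, n_sets = 100, maf_tol = 0.05,
                       rel_tol = 0.5, seed = NULL) {
  nt <- nrow(trait_snps)
  stopifnot(nt >= 1, nrow(pool) >= 1)
  if (any(pool$snp_id %in% trait_snps$snp_id)) {
    stop("candidate pool must be disjoint from the trait SNPs")
  }
  if (n_sets * nt > nrow(pool)) {
    stop(sprintf("matching capacity exceeded: %d sets x %d SNPs > %d pool candidates",
                 n_sets, nt, nrow(pool)))
  }
  eligible_for <- function(i, maf_tol, rel_tol, avail) {
    t <- trait_snps[i, ]
    rel_ok <- function(x, target) {
      abs(x - target) <= rel_tol_cur * pmax(abs(target), 1e-9)
    }
    rel_tol_cur <- rel_tol
    which(avail &
            abs(pool$maf - t$maf) <= maf_tol &
            rel_ok(pool$gene_density, t$gene_density) &
            rel_ok(pool$dist_nearest_gene, t$dist_nearest_gene) &
            rel_ok(pool$n_proxies, t$n_proxies))
  }
  with_seed(seed, {
    lapply(seq_len(n_sets), function(set) {
      avail <- rep(TRUE, nrow(pool))
      rows <- integer(nt)
      for (i in seq_len(nt)) {
        mt <- maf_tol; rt <- rel_tol
        cand <- eligible_for(i, mt, rt, avail)
        while (length(cand) == 0) {
          mt <- mt * 2; rt <- rt * 2
          if (rt > 64) stop("candidate pool exhausted for trait SNP ", trait_snps$snp_id[i])
          message("widening matching tolerances for ", trait_snps$snp_id[i],
                  " (maf +/- ", mt, ", rel +/- ", rt, ")")
          cand <- eligible_for(i, mt, rt, avail)
        }
        rows[i] <- if (length(cand) == 1) cand else sample(cand, 1)
        avail[rows[i]] <- FALSE
      }
      pool[rows, , drop = FALSE]
    })
  })
}

#' Distance of SNPs to the nearest TAD boundary, against matched nulls
#'
#' Boundaries are extended with a 10-kb outward buffer on both sides; the
#' distance of a SNP inside a buffered boundary is 0, otherwise it is the
#' bp gap to the nearest buffered boundary edge.  The observed median
#' distance of the trait SNPs is compared to the medians of the matched
#' control sets; the empirical P value uses the pseudo-counted rank
#' `(#{control medians <= observed} + 1) / (n_sets + 1)`, so it is never 0
#' and never exceeds 1.
#'
#' @param snp_pos data.frame with `chrom`, `pos` for the trait SNPs.
#' @param tads a [call_boundaries()] result (or data.frame of boundaries
#'   with `pos`; single-chromosome).
#' @param matched_sets list of control data.frames (`chrom`, `pos`), each
#'   with the trait set's cardinality (see [match_snps()]).
#' @param buffer outward boundary buffer in bp (default 10 kb).
#' @return list with `observed_median`, `control_medians`, `empirical_p`,
#'   `distances`.
#' @export
boundary_distance_test <- function(snp_pos, tads, matched_sets, buffer = 1e4) {
  bpos <- if (inherits(tads, "tad_set")) tads$boundaries$pos else tads$pos
  if (length(bpos) == 0) stop("no TAD boundaries to measure distances against")
  bchrom <- if (inherits(tads, "tad_set")) tads$chrom else NULL
  n_trait <- nrow(snp_pos)
  filter_chrom <- function(s) {
    if (is.null(bchrom) || is.null(s$chrom)) return(s)
    drop <- s$chrom != bchrom
    if (any(drop)) {
      message(sum(drop), " SNP(s) on chromosomes without boundaries excluded")
    }
    s[!drop, , drop = FALSE]
  }
  dist_to_boundary <- function(pos) {
    pmax(vapply(pos, function(p) min(abs(p - bpos)), 0) - buffer, 0)
  }
  d_obs <- dist_to_boundary(filter_chrom(snp_pos)$pos)
  obs <- median(d_obs)
  ctrl <- vapply(matched_sets, function(s) {
    stopifnot(nrow(s) == n_trait)
    median(dist_to_boundary(filter_chrom(s)$pos))
  }, 0)
  list(observed_median = obs, control_medians = ctrl,
       empirical_p = (sum(ctrl <= obs) + 1) / (length(ctrl) + 1),
       distances = d_obs)
}
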