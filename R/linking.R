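#' Hi-C read support for a candidate loop between two anchors
#'
#' Support is the sum of raw contact counts over all bin pairs (i, j)
#' where bin i overlaps the first padded anchor and bin j the second (the
#' raw matrix is symmetric, so both anchor orientations are covered).
#' When the padded anchors share a bin the support would mix self-ligation
#' signal with loop signal, so it is undefined and the candidate is
#' dropped by the caller.
#'
#' @param cm a [contact_matrix()] (raw counts are used).
#' @param anchor1,anchor2 single-row [genomic_intervals()] (or lists with
#'   `start`/`end`) on the matrix chromosome.
#' @param pad bp added on both sides of each anchor (default 5 kb).
#' @param quiet suppress the message emitted when the padded anchors
#'   overlap.
#' @return numeric read support, or `NA` (with a message) when the padded
#'   anchors overlap.
#' @export
count_loop_support <- function(cm, anchor1, anchor2, pad = 5000, quiet = FALSE) {
  stopifnot(inherits(cm, "contact_matrix"), pad >= 0)
  bins_of <- function(a) {
    lo <- max(a$start - pad, 0); hi <- a$end + pad
    from <- floor(lo / cm$bin_size) + 1
    to <- min(ceiling(hi / cm$bin_size), cm$n_bins)
    if (from > cm$n_bins || to < from) integer(0) else from:to
  }
  i <- bins_of(anchor1); j <- bins_of(anchor2)
  if (length(i) == 0 || length(j) == 0) return(0)
  if (i[1] <= j[length(j)] && j[1] <= i[length(i)]) {
    if (!quiet) message("padded anchors overlap; loop support undefined")
    return(NA_real_)
  }
  sum(cm$raw[i, j, drop = FALSE])
}

#' Build SNP-peak-gene link records through loop support and eQTL evidence
#'
#' Candidate combinations are (SNP contained in an open-chromatin peak) x
#' (gene with a promoter on the same chromosome).  Each candidate is
#' scored and filtered by the cascade: (1) chromatin-loop read support
#' between the peak and the promoter of at least `support_min` (>= 20
#' Hi-C reads), (2) the gene is expressed and above the bottom expression
#' percentile (`expr_pct_min`, strict), (3) the SNP is an eQTL for the
#' gene at `eqtl_p_max` (strict).  `passes_standard` is the conjunction of
#' the three (order-independent); `passes_stringent` additionally requires
#' a differential peak, a differential gene and the stringent eQTL
#' threshold.
#'
#' @param snps SNP position set from [expand_ld()] (`snp_id`, `chrom`,
#'   `pos`, `sentinel_id`, `trait`); every SNP must carry a sentinel
#'   (locus) id.
#' @param peaks [genomic_intervals()] of open-chromatin peaks.
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `promoter_start`,
#'   `promoter_end`, `expressed`, `expression_rank_percentile`).
#' @param cm raw [contact_matrix()] used for loop support.
#' @param eqtl data.frame (`snp_id`, `gene_id`, `p`).
#' @param support_min minimum Hi-C read support (default 20).
#' @param expr_pct_min genes at or below this expression-rank percentile
#'   are excluded (default 10).
#' @param eqtl_p_max,stringent_eqtl_p_max standard and stringent eQTL
#'   P-value thresholds (strict; defaults 1e-3 and 1e-5).
#' @param pad anchor padding in bp for [count_loop_support()].
#' @param differential_peaks,differential_genes optional character ids of
#'   differential features (default: none).
#' @return data.frame of link records: `snp_id`, `trait`, `locus_id`,
#'   `peak_id`, `peak_start`, `peak_end`, `gene_id`, `read_support`,
#'   `eqtl_p`, `peak_is_differential`, `gene_is_differential`,
#'   `pass_support`, `pass_expression`, `pass_eqtl`, `passes_standard`,
#'   `passes_stringent`, `distance` (bp between peak and promoter
#'   midpoints).
#' @export
build_links <- function(snps, peaks, genes, cm, eqtl,
                        support_min = 20, expr_pct_min = 10,
                        eqtl_p_max = 1e-3, stringent_eqtl_p_max = 1e-5,
                        pad = 5000,
                        differential_peaks = character(),
                        differential_genes = character()) {
  if (any(is.na(snps$sentinel_id))) {
    stop("SNP without sentinel mapping: panel integrity violated")
  }
  peak_idx <- point_in_interval(snps$chrom, snps$pos, peaks)
  in_peak <- which(!is.na(peak_idx))
  if (length(in_peak) == 0) return(empty_links())
  # candidate pairs: SNP-bearing peak x gene on the same chromosome
  cand <- do.call(rbind, lapply(in_peak, function(si) {
    gsel <- which(genes$chrom == snps$chrom[si])
    if (length(gsel) == 0) return(NULL)
    cbind(si = si, gi = gsel)
  }))
  if (is.null(cand)) return(empty_links())
  si <- cand[, "si"]; gi <- cand[, "gi"]; pi <- peak_idx[si]
  support <- vapply(seq_len(nrow(cand)), function(k) {
    count_loop_support(cm, list(start = peaks$start[pi[k]], end = peaks$end[pi[k]]),
                       list(start = genes$promoter_start[gi[k]],
                            end = genes$promoter_end[gi[k]]),
                       pad = pad, quiet = TRUE)
  }, 0)
  keep <- !is.na(support) # overlapping padded anchors: dropped
  if (any(!keep)) {
    message(sum(!keep), " candidate(s) dropped: padded anchors overlap")
  }
  si <- si[keep]; gi <- gi[keep]; pi <- pi[keep]; support <- support[keep]
  ep <- eqtl$p[match(paste(snps$snp_id[si], genes$gene_id[gi]),
                     paste(eqtl$snp_id, eqtl$gene_id))]
  pct <- genes$expression_rank_percentile[gi]
  pass_support <- support >= support_min
  pass_expr <- genes$expressed[gi] & !is.na(pct) & pct > expr_pct_min
  pass_eqtl <- !is.na(ep) & ep < eqtl_p_max
  peak_diff <- peaks$id[pi] %in% differential_peaks
  gene_diff <- genes$gene_id[gi] %in% differential_genes
  std <- pass_support & pass_expr & pass_eqtl
  out <- data.frame(
    snp_id = snps$snp_id[si], trait = snps$trait[si],
    locus_id = snps$sentinel_id[si],
    peak_id = peaks$id[pi], peak_start = peaks$start[pi],
    peak_end = peaks$end[pi],
    gene_id = genes$gene_id[gi], read_support = support, eqtl_p = ep,
    peak_is_differential = peak_diff, gene_is_differential = gene_diff,
    pass_support = pass_support, pass_expression = pass_expr,
    pass_eqtl = pass_eqtl, passes_standard = std,
    passes_stringent = std & peak_diff & gene_diff & !is.na(ep) &
      ep < stringent_eqtl_p_max,
    distance = abs((peaks$start[pi] + peaks$end[pi]) / 2 -
                     (genes$promoter_start[gi] + genes$promoter_end[gi]) / 2),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_links <- function() {
  data.frame(snp_id = character(), trait = character(), locus_id = character(),
             peak_id = character(), peak_start = numeric(), peak_end = numeric(),
             gene_id = character(), read_support = integer(), eqtl_p = numeric(),
             peak_is_differential = logical(), gene_is_differential = logical(),
             pass_support = logical(), pass_expression = logical(),
             pass_eqtl = logical(), passes_standard = logical(),
             passes_stringent = logical(), distance = numeric(),
             stringsAsFactors = FALSE)
}

#' Summarise passing link records
#'
#' @param links [build_links()] output.
#' @param which filter flag to summarise (`"standard"` or `"stringent"`).
#' @return list with `n_combinations`, `loci_per_trait` (distinct sentinel
#'   loci among passing links, per trait), `distance_mean_bp`,
#'   `distance_sd_bp` (population SD).  An empty passing set yields zero
#'   counts with `NA` distances.
#' @export
summarize_links <- function(links, which = c("standard", "stringent")) {
  which <- match.arg(which)
  flag <- if (which == "standard") links$passes_standard else links$passes_stringent
  pass <- links[flag, , drop = FALSE]
  if (nrow(pass) == 0) {
    return(list(n_combinations = 0L, loci_per_trait = integer(0),
                distance_mean_bp = NA_real_, distance_sd_bp = NA_real_))
  }
  pop_sd <- sqrt(mean((pass$distance - mean(pass$distance))^2))
  list(n_combinations = nrow(pass),
       loci_per_trait = vapply(split(pass$locus_id, pass$trait),
                               function(x) length(unique(x)), 0L),
       distance_mean_bp = mean(pass$distance),
       distance_sd_bp = pop_sd)
}
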