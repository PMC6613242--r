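#' Median-of-ratios count normalisation
#'
#' Per-sample size factor = median across features (restricted to features
#' with a nonzero geometric mean) of `count / geometric mean of the
#' feature`; normalised count = `count / size factor`.  This is the
#' standard median-of-ratios normalisation used before fold-change and
#' differential testing.
#'
#' @param counts non-negative matrix, features x samples.
#' @return list with `size_factors` (named per sample) and `normalized`.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("all-zero sample: cannot compute size factors")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no feature has a nonzero geometric mean")
  ratios <- counts[use, , drop = FALSE] / exp(log_gm[use])
  sf <- apply(ratios, 2, median)
  list(size_factors = setNames(sf, colnames(counts)),
       normalized = sweep(counts, 2, sf, "/"))
}

#' Differential test for one condition comparison
#'
#' Computes per-feature log10 fold-changes on normalised condition means
#' (pseudocount 0.5), a two-sided Welch t-test on log2-normalised replicate
#' values, Benjamini-Hochberg adjustment within the comparison, and the
#' classification rule: `up` iff `fdr < fdr_threshold` and
#' `log10_fc > lfc_threshold` (both strict); `down` symmetrical;
#' `unchanged` otherwise.  Defaults reproduce the FDR < 0.1% and
#' |log10 FC| > 0.3 rule.
#'
#' @param counts feature x sample count matrix with sample names
#'   `COND_rep`.
#' @param samples data.frame with columns `condition`, `replicate`, one row
#'   per column of `counts`.
#' @param comparison character pair `c(cond1, cond2)`; fold-change is
#'   `log10(mean2 / mean1)`.
#' @param fdr_threshold,lfc_threshold classification thresholds.
#' @param pseudocount added to normalised means (and replicate values)
#'   before taking logs.
#' @param log_base base of the reported fold-change (default 10).
#' @return data.frame with `feature_id`, `comparison`, `log10_fc`,
#'   `p_value`, `fdr`, `class`.  With a single replicate in either
#'   condition the fold-change is still reported but `p_value`/`fdr` are
#'   `NA` and the class is `unchanged`.
#' @export
test_differential <- function(counts, samples, comparison,
                              fdr_threshold = 0.001, lfc_threshold = 0.3,
                              pseudocount = 0.5, log_base = 10) {
  stopifnot(length(comparison) == 2, nrow(samples) == ncol(counts))
  norm <- normalize_counts(counts)$normalized
  g1 <- which(samples$condition == comparison[1])
  g2 <- which(samples$condition == comparison[2])
  if (length(g1) == 0 || length(g2) == 0) {
    stop("comparison conditions not found in samples")
  }
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  lfc <- log((m2 + pseudocount) / (m1 + pseudocount), base = log_base)
  if (length(g1) >= 2 && length(g2) >= 2) {
    x1 <- log2(norm[, g1, drop = FALSE] + pseudocount)
    x2 <- log2(norm[, g2, drop = FALSE] + pseudocount)
    p <- welch_p(x1, x2)
  } else {
    p <- rep(NA_real_, nrow(counts))
  }
  fdr <- p.adjust(p, method = "BH")
  cls <- rep("unchanged", nrow(counts))
  sig <- !is.na(fdr) & fdr < fdr_threshold
  cls[sig & lfc > lfc_threshold] <- "up"
  cls[sig & lfc < -lfc_threshold] <- "down"
  data.frame(feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             comparison = paste0(comparison[1], "_vs_", comparison[2]),
             log10_fc = lfc, p_value = p, fdr = fdr, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorised two-sided Welch t-test over matrix rows
welch_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mu2 - mu1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  zero <- se2 == 0
  p[zero] <- ifelse(mu1[zero] == mu2[zero], 1, .Machine$double.xmin)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Union of differential features across comparisons
#'
#' A feature is differential overall iff its class is not `unchanged` in at
#' least one of the three condition comparisons (the "any of the 3 possible
#' comparisons" rule).
#'
#' @param tables list of [test_differential()] outputs covering an
#'   identical feature universe.
#' @return list with `features` (character vector of differential feature
#'   ids) and `per_comparison` (named list of per-comparison differential
#'   feature ids).
#' @export
union_differential <- function(tables) {
  stopifnot(length(tables) >= 1)
  universe <- sort(tables[[1]]$feature_id)
  for (tb in tables) {
    if (!identical(sort(tb$feature_id), universe)) {
      stop("differential tables cover different feature universes")
    }
  }
  per <- lapply(tables, function(tb) tb$feature_id[tb$class != "unchanged"])
  names(per) <- vapply(tables, function(tb) tb$comparison[1], "")
  list(features = sort(unique(unlist(per))), per_comparison = per)
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm = count * 1e9 / (length * total counts of the sample)`.
#'
#' @param counts feature x sample count matrix.
#' @param feature_lengths feature lengths in bp (> 0).
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, feature_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(feature_lengths) == nrow(counts))
  if (any(feature_lengths <= 0)) stop("feature lengths must be positive")
  totals <- colSums(counts)
  sweep(counts / feature_lengths, 2, totals, "/") * 1e9
}
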