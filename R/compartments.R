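#' Call A/B compartments on a balanced contact matrix
#'
#' Per-chromosome procedure: the balanced matrix is transformed to
#' observed/expected by dividing each entry by the mean of its diagonal,
#' the Pearson correlation matrix of the result is computed, and PC1 of
#' that correlation matrix is taken as the compartment eigenvector.  The
#' sign of PC1 is flipped, if necessary, so that positive values correlate
#' with gene-rich bins; contiguous bins of positive and negative PC1 are
#' then labelled A and B respectively.  PCA on the raw contacts would
#' recover distance decay, not compartments, hence the observed/expected
#' and correlation transforms.
#'
#' @param cm a balanced [contact_matrix()] (weights computed on demand).
#' @param gene_density a [binned_track()] of gene counts on the identical
#'   bin grid, used only to orient the sign of PC1.
#' @param min_bins chromosomes with fewer unmasked bins are not called
#'   (all-masked output with a warning).
#' @return list of class `compartment_track`: `pc1` ([binned_track()]),
#'   `labels` (per-bin `"A"`/`"B"`/`NA`), `segments`
#'   ([genomic_intervals()] with `id` = label).
#' @export
call_compartments <- function(cm, gene_density, min_bins = 20) {
  stopifnot(inherits(cm, "contact_matrix"), inherits(gene_density, "binned_track"),
            gene_density$n_bins == cm$n_bins, gene_density$bin_size == cm$bin_size)
  n <- cm$n_bins
  keep <- !cm$mask
  if (sum(keep) < min_bins) {
    warning("fewer than ", min_bins, " unmasked bins; compartments not called")
    return(new_compartment_track(cm, rep(NA_real_, n)))
  }
  b <- balanced(cm)[keep, keep, drop = FALSE]
  oe <- obs_over_exp(b)
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  pc1 <- prcomp(cc, center = TRUE, scale. = FALSE)$x[, 1]
  gd <- gene_density$values[keep]
  r <- suppressWarnings(cor(pc1, gd))
  if (is.finite(r) && r < 0) pc1 <- -pc1
  values <- rep(NA_real_, n)
  values[keep] <- pc1
  new_compartment_track(cm, values)
}

# divide each entry by the mean of its |i-j| diagonal
obs_over_exp <- function(b) {
  n <- nrow(b)
  s <- abs(outer(seq_len(n), seq_len(n), `-`))
  dmean <- vapply(0:(n - 1), function(d) mean(b[s == d]), 0)
  oe <- b / dmean[s + 1]
  oe[!is.finite(oe)] <- 0
  oe
}

new_compartment_track <- function(cm, pc1_values) {
  labels <- rep(NA_character_, cm$n_bins)
  labels[!is.na(pc1_values) & pc1_values > 0] <- "A"
  labels[!is.na(pc1_values) & pc1_values < 0] <- "B"
  # exact PC1 = 0 ties inherit the previous unmasked label; leading ties masked
  tie <- which(!is.na(pc1_values) & pc1_values == 0)
  for (i in tie) {
    prev <- which(!is.na(labels[seq_len(i - 1)]))
    labels[i] <- if (length(prev)) labels[max(prev)] else NA_character_
  }
  structure(list(pc1 = binned_track(cm$chrom, cm$bin_size, pc1_values),
                 labels = labels,
                 segments = label_segments(cm$chrom, cm$bin_size, labels)),
            class = "compartment_track")
}

# maximal runs of a constant label as intervals (masked bins break runs)
label_segments <- function(chrom, bin_size, labels) {
  n <- length(labels)
  if (n == 0 || all(is.na(labels))) return(genomic_intervals())
  key <- ifelse(is.na(labels), "<NA>", labels)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != "<NA>"
  genomic_intervals(chrom, (starts[keep] - 1) * bin_size,
                    ends[keep] * bin_size, id = r$values[keep])
}

#' Compare compartments between two conditions
#'
#' @param c1,c2 `compartment_track` objects on identical bin grids.
#' @return list of class `switch_set`: `A_to_B` and `B_to_A`
#'   ([genomic_intervals()] of merged switched runs, labelled A in
#'   condition 1 / B in condition 2 and vice versa),
#'   `genome_fraction_switched` (switched / common unmasked bins),
#'   `pc1_correlation` (Pearson r of the PC1 vectors over common unmasked
#'   bins), and the per-bin `switched` logical.
#' @export
compare_compartments <- function(c1, c2) {
  t1 <- c1$pc1; t2 <- c2$pc1
  if (t1$n_bins != t2$n_bins || t1$bin_size != t2$bin_size) {
    stop("compartment tracks are on different bin grids")
  }
  common <- !is.na(c1$labels) & !is.na(c2$labels)
  switched <- common & c1$labels != c2$labels
  a2b <- common & c1$labels == "A" & c2$labels == "B"
  b2a <- common & c1$labels == "B" & c2$labels == "A"
  run_iv <- function(flag) {
    if (!any(flag)) return(genomic_intervals())
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values
    genomic_intervals(t1$chrom, (starts[keep] - 1) * t1$bin_size,
                      ends[keep] * t1$bin_size)
  }
  structure(list(
    A_to_B = run_iv(a2b), B_to_A = run_iv(b2a),
    genome_fraction_switched = sum(switched) / sum(common),
    pc1_correlation = cor(t1$values[common], t2$values[common]),
    switched = switched
  ), class = "switch_set")
}

#' Enrichment ratio of two class fractions
#'
#' @param p_hat fraction of in-switch features carrying the class.
#' @param p0 background fraction of the class.
#' @return `p_hat / p0`.
#' @export
enrichment_ratio <- function(p_hat, p0) p_hat / p0

#' Enrichment of a feature class in switching compartments
#'
#' Features are assigned to switch intervals by midpoint containment.  For
#' the target class, `p_hat` = fraction of in-switch features with the
#' class, `p0` = background fraction, enrichment = `p_hat / p0`, and the
#' P value is a one-sided exact binomial tail in the direction of the
#' observed enrichment (upper tail `P(X >= k)` when enrichment > 1).
#'
#' @param features [genomic_intervals()] of classified features.
#' @param classes character class per feature (e.g. `up`, `down`, `open`,
#'   `close`, `other`).
#' @param switch_intervals [genomic_intervals()] of one switch direction.
#' @param target_class class whose enrichment is tested.
#' @param background_classes class labels of the background universe
#'   (defaults to `classes`).
#' @param alternative `"auto"` (one-sided in the direction of the observed
#'   enrichment), `"greater"` or `"less"`.
#' @return list with `k`, `n`, `p_hat`, `p0`, `enrichment`, `p_binomial`.
#'   With no in-switch features (`n = 0`) the result is flagged
#'   `undefined = TRUE` rather than raising an error.
#' @export
switching_enrichment <- function(features, classes, switch_intervals,
                                 target_class,
                                 background_classes = classes,
                                 alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(classes) == nrow(features))
  mid <- floor(interval_midpoint(features))
  hit <- !is.na(point_in_interval(features$chrom, mid, switch_intervals))
  n <- sum(hit)
  k <- sum(hit & classes == target_class)
  p0 <- mean(background_classes == target_class)
  if (n == 0 || p0 == 0) {
    return(list(k = as.integer(k), n = as.integer(n), p_hat = if (n > 0) k / n else NA_real_,
                p0 = p0, enrichment = NA_real_, p_binomial = NA_real_,
                undefined = TRUE))
  }
  p_hat <- k / n
  enr <- enrichment_ratio(p_hat, p0)
  side <- switch(alternative, greater = "greater", less = "less",
                 auto = if (enr >= 1) "greater" else "less")
  p <- if (side == "greater") pbinom(k - 1, n, p0, lower.tail = FALSE)
       else pbinom(k, n, p0)
  list(k = k, n = n, p_hat = p_hat, p0 = p0, enrichment = enr,
       p_binomial = p, undefined = FALSE)
}
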