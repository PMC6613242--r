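#' Insulation score along a balanced contact matrix
#'
#' For each bin i the raw insulation score is the mean of the balanced
#' entries in the square `[i-w, i-1] x [i+1, i+w]` with
#' `w = square_size / bin_size` ("mean" insulation mode); the normalised
#' score is `log2(score / chromosome mean of scores)`.  Bins whose square
#' extends past a chromosome end, falls on a masked bin, or is more than
#' 50% masked carry no score.
#'
#' @param cm a balanced [contact_matrix()] (weights computed on demand),
#'   typically at 10-kb resolution.
#' @param square_size side of the insulation square in bp (default 500 kb);
#'   must be a multiple of the bin size.
#' @return list of class `insulation_track` with `score` and `normalized`
#'   ([binned_track()]s), `mask` (the matrix low-coverage mask) and
#'   `bin_size`.
#' @export
insulation_score <- function(cm, square_size = 5e5) {
  stopifnot(inherits(cm, "contact_matrix"))
  w <- square_size / cm$bin_size
  if (w != round(w) || w < 1) stop("square_size must be a positive multiple of bin_size")
  w <- as.integer(w)
  b <- balanced(cm)
  n <- cm$n_bins
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n || cm$mask[i]) next
    sub <- b[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    if (mean(is.na(sub)) > 0.5) next
    score[i] <- mean(sub, na.rm = TRUE)
  }
  normalized <- suppressWarnings(log2(score / mean(score, na.rm = TRUE)))
  normalized[!is.finite(normalized)] <- NA_real_
  structure(list(score = binned_track(cm$chrom, cm$bin_size, score),
                 normalized = binned_track(cm$chrom, cm$bin_size, normalized),
                 mask = cm$mask, bin_size = cm$bin_size, chrom = cm$chrom),
            class = "insulation_track")
}

#' Call TAD boundaries from an insulation track
#'
#' The delta vector at bin i is the mean normalised insulation over
#' `(i, i+span]` minus the mean over `[i-span, i)`; insulation minima are
#' the points where delta crosses zero from negative to positive.  The
#' boundary is placed at whichever of the two flanking bins has the lower
#' insulation, its strength is the swing of the delta vector around the
#' crossing (nearest delta local maximum right of the crossing minus
#' nearest local minimum left of it), and candidates are kept only when
#' the strength strictly exceeds `noise_threshold`.  Candidates within
#' `margin` bins of a masked (low-coverage) bin are dropped.
#'
#' @param ins an [insulation_score()] result.
#' @param delta_span span of the delta windows in bp (default 200 kb).
#' @param noise_threshold minimum boundary strength (strict; default 0.1).
#' @param margin masked-proximity filter in bins (default 3).
#' @param excluded_regions optional [genomic_intervals()] (e.g. centromere
#'   annotations); TADs overlapping them are excluded.
#' @return list of class `tad_set` with `boundaries` (data.frame `bin`,
#'   `pos` (bp, boundary-bin end), `strength`), `tads`
#'   ([genomic_intervals()] between consecutive boundaries) and
#'   `excluded_regions`.  With no boundary the single TAD spanning the
#'   unmasked extent is returned with a warning.
#' @export
call_boundaries <- function(ins, delta_span = 2e5, noise_threshold = 0.1,
                            margin = 3, excluded_regions = NULL) {
  stopifnot(inherits(ins, "insulation_track"))
  v <- ins$normalized$values
  n <- length(v)
  s <- delta_span / ins$bin_size
  if (s != round(s) || s < 1) stop("delta_span must be a positive multiple of bin_size")
  s <- as.integer(s)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - s < 1 || i + s > n) next
    right <- v[(i + 1):(i + s)]
    left <- v[(i - s):(i - 1)]
    if (all(is.na(right)) || all(is.na(left))) next
    delta[i] <- mean(right, na.rm = TRUE) - mean(left, na.rm = TRUE)
  }
  cand <- which(!is.na(delta[-n]) & !is.na(delta[-1]) &
                  delta[-n] < 0 & delta[-1] >= 0)
  keep_bin <- integer(0); keep_strength <- numeric(0)
  for (i in cand) {
    # strength: delta swing across the crossing
    hi <- local_extremum(delta, i + 1, +1L, find_max = TRUE)
    lo <- local_extremum(delta, i, -1L, find_max = FALSE)
    if (is.na(hi$value) || is.na(lo$value)) next
    strength <- hi$value - lo$value
    if (!(strength > noise_threshold)) next
    # boundary bin: insulation minimum between the flanking delta extrema
    win <- lo$index:hi$index
    vv <- v[win]
    b <- if (all(is.na(vv))) i else win[which.min(replace(vv, is.na(vv), Inf))]
    lo_b <- max(1, b - margin); hi_b <- min(n, b + margin)
    if (any(ins$mask[lo_b:hi_b])) next
    keep_bin <- c(keep_bin, b); keep_strength <- c(keep_strength, strength)
  }
  # collapse boundaries called on adjacent bins (same crossing) to the strongest
  if (length(keep_bin) > 1) {
    ord <- order(keep_bin)
    keep_bin <- keep_bin[ord]; keep_strength <- keep_strength[ord]
    drop <- rep(FALSE, length(keep_bin))
    for (k in seq_along(keep_bin)[-1]) {
      if (keep_bin[k] - keep_bin[k - 1] <= 1) {
        drop[if (keep_strength[k] >= keep_strength[k - 1]) k - 1 else k] <- TRUE
      }
    }
    keep_bin <- keep_bin[!drop]; keep_strength <- keep_strength[!drop]
  }
  pos <- keep_bin * ins$bin_size
  boundaries <- data.frame(bin = keep_bin, pos = pos, strength = keep_strength)
  unmasked <- which(!ins$mask)
  if (nrow(boundaries) == 0) {
    warning("no boundaries called; returning a single TAD over the unmasked extent")
    tads <- genomic_intervals(ins$chrom, (min(unmasked) - 1) * ins$bin_size,
                              max(unmasked) * ins$bin_size)
  } else if (nrow(boundaries) == 1) {
    tads <- genomic_intervals()
  } else {
    tads <- genomic_intervals(ins$chrom, pos[-length(pos)], pos[-1])
  }
  if (!is.null(excluded_regions) && nrow(tads) > 0 && nrow(excluded_regions) > 0) {
    hit <- unique(intersect_intervals(tads, excluded_regions)$a_idx)
    if (length(hit)) tads <- tads[-hit, , drop = FALSE]
  }
  structure(list(boundaries = boundaries, tads = tads,
                 excluded_regions = excluded_regions, chrom = ins$chrom,
                 bin_size = ins$bin_size),
            class = "tad_set")
}

# nearest local extremum of `x` scanning from `start` in direction `dir`,
# following the monotone run; NA value when the scan starts on an NA
local_extremum <- function(x, start, dir, find_max) {
  n <- length(x)
  k <- start
  if (k < 1 || k > n || is.na(x[k])) return(list(value = NA_real_, index = k))
  repeat {
    nxt <- k + dir
    if (nxt < 1 || nxt > n || is.na(x[nxt])) return(list(value = x[k], index = k))
    better <- if (find_max) x[nxt] >= x[k] else x[nxt] <= x[k]
    if (!better) return(list(value = x[k], index = k))
    k <- nxt
  }
}

#' Fraction of TAD boundaries without a counterpart in another condition
#'
#' A boundary of `t1` is matched iff a boundary of `t2` lies within
#' `buffer` bp (inclusive, mirroring the 20-kb outward buffer used to
#' classify boundaries as stable between conditions).
#'
#' @param t1,t2 [call_boundaries()] results on the same genome.
#' @param buffer matching tolerance in bp (default 20 kb).
#' @return list with `changed_fraction`, `n_boundaries`, `matched`
#'   (logical per t1 boundary) and `nearest_distance` (bp).
#' @export
boundary_stability <- function(t1, t2, buffer = 2e4) {
  p1 <- t1$boundaries$pos
  p2 <- t2$boundaries$pos
  if (length(p1) == 0) {
    return(list(changed_fraction = NA_real_, n_boundaries = 0L,
                matched = logical(0), nearest_distance = numeric(0)))
  }
  nd <- if (length(p2)) vapply(p1, function(p) min(abs(p - p2)), 0) else rep(Inf, length(p1))
  matched <- nd <= buffer
  list(changed_fraction = mean(!matched), n_boundaries = length(p1),
       matched = matched, nearest_distance = nd)
}

#' Size-normalised metaprofile of features across TADs
#'
#' Each TAD is extended by `flank` bp on both sides (so that boundary
#' positions map to fixed relative coordinates despite TADs differing in
#' size), mapped to `[0, 1]`, and split into `n_bins` relative bins;
#' feature midpoints are accumulated and converted to a density per kb,
#' then averaged across TADs.
#'
#' @param tads a [call_boundaries()] result or [genomic_intervals()] of
#'   TADs.
#' @param features [genomic_intervals()] (e.g. CTCF peaks, TSSs,
#'   enhancers, SNP positions as width-1 intervals).
#' @param flank bp added on either side before normalising (default 35 kb).
#' @param n_bins number of relative-position bins (default 100).
#' @return numeric vector of length `n_bins`: mean feature density
#'   (features per kb) per relative position.
#' @export
tad_metaprofile <- function(tads, features, flank = 3.5e4, n_bins = 100) {
  iv <- if (inherits(tads, "tad_set")) tads$tads else tads
  stopifnot(nrow(iv) > 0)
  mids <- interval_midpoint(features)
  prof <- matrix(0, nrow(iv), n_bins)
  for (k in seq_len(nrow(iv))) {
    ext_start <- iv$start[k] - flank
    width <- (iv$end[k] - iv$start[k]) + 2 * flank
    sel <- features$chrom == iv$chrom[k] & mids >= ext_start & mids < ext_start + width
    if (any(sel)) {
      rel <- (mids[sel] - ext_start) / width
      bin <- pmin(floor(rel * n_bins) + 1, n_bins)
      prof[k, ] <- tabulate(bin, n_bins)
    }
    prof[k, ] <- prof[k, ] / (width / n_bins / 1000) # density per kb
  }
  colMeans(prof)
}

#' Score called boundaries against planted truth
#'
#' Helper for simulation studies: precision and recall of called boundary
#' positions against planted ones, with a bin tolerance, restricted to the
#' callable region (chromosome ends where the insulation square or delta
#' window cannot be formed are excluded, as chromosome-end regions are
#' excluded from TAD analyses).
#'
#' @param called,truth_bp boundary positions in bp.
#' @param bin_size matrix bin size in bp.
#' @param tol_bins match tolerance in bins (default 1).
#' @param callable_range optional `c(lo, hi)` bp range; truth boundaries
#'   outside it are not scored.
#' @return list with `precision`, `recall`, `n_called`, `n_truth`.
#' @export
score_boundaries <- function(called, truth_bp, bin_size, tol_bins = 1,
                             callable_range = NULL) {
  if (!is.null(callable_range)) {
    truth_bp <- truth_bp[truth_bp >= callable_range[1] & truth_bp <= callable_range[2]]
    called <- called[called >= callable_range[1] & called <= callable_range[2]]
  }
  tol <- tol_bins * bin_size
  tp_called <- if (length(truth_bp)) {
    vapply(called, function(p) min(abs(p - truth_bp)) <= tol, TRUE)
  } else rep(FALSE, length(called))
  rec <- if (length(truth_bp)) {
    mean(vapply(truth_bp, function(p) length(called) > 0 && min(abs(called - p)) <= tol, TRUE))
  } else NA_real_
  list(precision = if (length(called)) mean(tp_called) else NA_real_,
       recall = rec, n_called = length(called), n_truth = length(truth_bp))
}
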