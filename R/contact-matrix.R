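#' Construct a per-chromosome Hi-C contact matrix
#'
#' Symmetric binned contact counts for one chromosome, together with the
#' low-coverage bin mask and (once computed) Knight-Ruiz balancing weights.
#'
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param raw symmetric non-negative numeric matrix of contact counts.
#' @param mask logical per-bin exclusion vector; defaults to masking bins
#'   with zero marginal count.
#' @param weights optional per-bin balancing weights (`NA` at masked bins).
#' @return list of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, raw, mask = NULL, weights = NULL) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == ncol(raw))
  if (any(raw < 0)) stop("contact counts must be non-negative")
  if (!isSymmetric(unname(raw), tol = 0)) stop("raw contact matrix must be symmetric")
  n <- nrow(raw)
  if (is.null(mask)) mask <- rowSums(raw) == 0
  stopifnot(length(mask) == n)
  if (!is.null(weights)) stopifnot(length(weights) == n)
  structure(list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
                 raw = unname(raw), mask = as.logical(mask),
                 weights = weights, n_bins = n),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d x %d bins of %g bp (%d masked, %s)\n",
              x$chrom, x$n_bins, x$n_bins, x$bin_size, sum(x$mask),
              if (is.null(x$weights)) "unbalanced" else "balanced"))
  invisible(x)
}

#' Load a contact matrix from sparse COO text
#'
#' Expects whitespace/tab-separated lines `bin_i_start  bin_j_start  count`
#' (upper or lower triangle, or both); the matrix is symmetrised by
#' mirroring.  Bins with zero marginal, and bins whose marginal falls below
#' a low-coverage quantile of the nonzero marginals, are masked.
#'
#' @param path COO text file.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp; bin starts must be multiples of it.
#' @param chrom chromosome name to attach.
#' @param mask_quantile bins with marginal below this quantile of the
#'   nonzero marginals are masked (default 0.02, mirroring common Hi-C
#'   practice for sparse-bin exclusion).
#' @return a [contact_matrix()].
#' @export
load_matrix <- function(path, chrom_length, bin_size, chrom = "chr1",
                        mask_quantile = 0.02) {
  n <- ceiling(chrom_length / bin_size)
  raw <- matrix(0, n, n)
  tab <- tryCatch(read.table(path, header = FALSE,
                             colClasses = c("numeric", "numeric", "numeric")),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0) {
    if (any(tab[[1]] %% bin_size != 0 | tab[[2]] %% bin_size != 0)) {
      stop("COO bin start not a multiple of bin_size = ", bin_size)
    }
    i <- tab[[1]] / bin_size + 1
    j <- tab[[2]] / bin_size + 1
    if (any(i > n | j > n)) stop("COO bin start beyond chromosome end")
    raw[cbind(i, j)] <- tab[[3]]
    raw[cbind(j, i)] <- tab[[3]]
  }
  cm <- contact_matrix(chrom, bin_size, raw)
  cm$mask <- low_coverage_mask(raw, mask_quantile)
  cm
}

low_coverage_mask <- function(raw, mask_quantile = 0.02) {
  marg <- rowSums(raw)
  mask <- marg == 0
  nz <- marg[!mask]
  if (length(nz) && mask_quantile > 0) {
    thr <- quantile(nz, mask_quantile, names = FALSE)
    mask <- mask | marg < thr
  }
  mask
}

#' Write a contact matrix as sparse COO text (upper triangle)
#' @param cm a [contact_matrix()].
#' @param path output path.
#' @export
write_matrix <- function(cm, path) {
  idx <- which(upper.tri(cm$raw, diag = TRUE) & cm$raw != 0, arr.ind = TRUE)
  df <- data.frame(format_num((idx[, 1] - 1) * cm$bin_size),
                   format_num((idx[, 2] - 1) * cm$bin_size),
                   format_num(cm$raw[idx]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Knight-Ruiz matrix balancing
#'
#' Computes per-bin weights `w` such that the balanced matrix
#' `b[i,j] = w[i] * raw[i,j] * w[j]` has all unmasked row sums equal to 1,
#' using the Knight-Ruiz inner-outer Newton iteration (conjugate-gradient
#' inner solves).  Balancing corrects bin-wise coverage biases and is the
#' standard normalisation applied to contact maps before any downstream
#' analysis.
#'
#' @param cm a [contact_matrix()].
#' @param tol relative tolerance on the balanced row sums (default `1e-6`).
#' @param max_iter maximum outer Newton iterations.
#' @return the matrix with `$weights` filled (`NA` at masked bins).
#' @details Fails with the last residual if the iteration does not converge,
#'   or if the unmasked submatrix has an all-zero row (structurally
#'   unbalanceable).
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(cm, "contact_matrix"))
  keep <- !cm$mask
  A <- cm$raw[keep, keep, drop = FALSE]
  if (nrow(A) == 0) stop("all bins are masked; nothing to balance")
  if (any(rowSums(A) == 0)) {
    stop("unmasked all-zero row: matrix is structurally unbalanceable; widen the mask")
  }
  x <- kr_core(A, tol = tol, max_iter = max_iter)
  w <- rep(NA_real_, cm$n_bins)
  w[keep] <- x
  cm$weights <- w
  cm
}

# Knight & Ruiz (2013) 'bnewt' algorithm: solve diag(x) A diag(x) e = e
kr_core <- function(A, tol = 1e-6, max_iter = 100, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  x <- e
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- drop(crossprod(rk))
  rho_km2 <- rho_km1
  rout <- rho_km1; rold <- rout
  i <- 0
  while (rout > rt) {
    i <- i + 1
    if (i > max_iter) {
      stop(sprintf("KR balancing did not converge in %d outer iterations (residual %.3e)",
                   max_iter, sqrt(rout)))
    }
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    p <- NULL; Z <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- drop(crossprod(rk, Z))
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / drop(crossprod(p, w))
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- drop(crossprod(rk, Z))
      if (k > 200) break # CG safety valve; outer loop restarts
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- drop(crossprod(rk))
    rho_km2 <- rho_km1
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

#' Balanced contact matrix
#'
#' @param cm a balanced [contact_matrix()] (see [kr_balance()]); if weights
#'   are absent they are computed with default settings.
#' @return dense matrix `w_i * raw_ij * w_j` with `NA` on masked rows/columns.
#' @export
balanced <- function(cm) {
  if (is.null(cm$weights)) cm <- kr_balance(cm)
  w <- cm$weights
  b <- cm$raw * tcrossprod(w)
  b[cm$mask, ] <- NA_real_
  b[, cm$mask] <- NA_real_
  b
}

#' Pearson correlation between replicate contact matrices
#'
#' @param a,b [contact_matrix()] objects on the same chromosome and bin
#'   grid.
#' @param exclude_diag drop the main diagonal (default `TRUE`): self-bin
#'   counts are dominated by fragment-level artefacts.
#' @return Pearson r over upper-triangle entries unmasked in both matrices.
#' @export
replicate_correlation <- function(a, b, exclude_diag = TRUE) {
  stopifnot(a$chrom == b$chrom, a$bin_size == b$bin_size, a$n_bins == b$n_bins)
  keep <- !(a$mask | b$mask)
  ut <- upper.tri(a$raw, diag = !exclude_diag) & outer(keep, keep, `&`)
  if (sum(ut) < 3) stop("fewer than 3 common unmasked entries")
  cor(a$raw[ut], b$raw[ut])
}

#' Pool replicate contact matrices
#'
#' Raw counts are summed entrywise (merging replicates to increase
#' statistical power); the mask is the union of the replicate masks and any
#' balancing weights are dropped so that balancing is recomputed on the
#' pooled counts.
#'
#' @param matrices list of [contact_matrix()] with identical chromosome and
#'   bin grid.
#' @return pooled [contact_matrix()].
#' @export
pool_replicates <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- matrices[[1]]
  raw <- matrix(0, ref$n_bins, ref$n_bins)
  mask <- rep(FALSE, ref$n_bins)
  for (m in matrices) {
    stopifnot(inherits(m, "contact_matrix"))
    if (m$chrom != ref$chrom || m$bin_size != ref$bin_size ||
        m$n_bins != ref$n_bins) {
      stop("replicate matrices differ in chromosome, bin size or shape")
    }
    raw <- raw + m$raw
    mask <- mask | m$mask
  }
  contact_matrix(ref$chrom, ref$bin_size, raw, mask = mask)
}
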