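# Independent brute-force oracles used across tests.  These deliberately
# use naive quadratic algorithms so they share no code path with the
# package implementations they check.

# all-pairs interval overlap under 0-based half-open arithmetic
brute_overlaps <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) data.frame(a_idx = integer(), b_idx = integer())
  else data.frame(a_idx = out[, 1], b_idx = out[, 2])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(200, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + width)
}

# Sinkhorn fixed-point balancing: alternately rescale rows/columns of a
# symmetric positive matrix until all row sums equal 1
sinkhorn_balance <- function(A, tol = 1e-12, max_iter = 1e5) {
  w <- rep(1, nrow(A))
  for (it in seq_len(max_iter)) {
    r <- as.vector((w * A) %*% w)
    if (max(abs(r - 1)) < tol) break
    w <- w / sqrt(r)
  }
  w
}

# naive mean of the off-diagonal square used by the insulation score
brute_insulation <- function(mat, w) {
  n <- nrow(mat)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    acc <- c()
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) acc <- c(acc, mat[a, b])
    out[i] <- mean(acc)
  }
  out
}

# step-up Benjamini-Hochberg by its defining formula
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    rank_i <- match(i, ord)
    adj[i] <- min(1, min(p[ord][rank_i:m] * m / (rank_i:m)))
  }
  adj
}

# insulation track built directly from a vector of normalised values, for
# boundary-caller tests that bypass matrix simulation
make_insulation <- function(values, bin_size = 1e4, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  structure(list(score = binned_track("chrT", bin_size, 2^values),
                 normalized = binned_track("chrT", bin_size, values),
                 mask = mask, bin_size = bin_size, chrom = "chrT"),
            class = "insulation_track")
}
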