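test_that("a constant matrix has zero normalised insulation at interior bins", {
  n <- 30
  cm <- contact_matrix("c", 1e4, matrix(5, n, n), mask = rep(FALSE, n))
  cm$weights <- rep(sqrt(1 / (5 * n)), n)
  ins <- insulation_score(cm, square_size = 5e4)
  interior <- 6:(n - 5)
  expect_equal(ins$normalized$values[interior], rep(0, length(interior)),
               tolerance = 1e-12)
  expect_true(all(is.na(ins$normalized$values[1:5])))
})

test_that("insulation scores equal the brute-force window mean", {
  for (seed in 1:4) {
    A <- withr::with_seed(seed, {
      A <- matrix(runif(1600, 0.1, 2), 40); A + t(A)
    })
    cm <- kr_balance(contact_matrix("c", 1e4, A, mask = rep(FALSE, 40)))
    ins <- insulation_score(cm, square_size = 5e4)
    brute <- brute_insulation(balanced(cm), 5L)
    got <- ins$score$values
    expect_equal(got[!is.na(got)], brute[!is.na(brute)], tolerance = 1e-12)
  }
})

test_that("two contact blocks produce the raw-score minimum at their junction", {
  n <- 60
  A <- matrix(0, n, n)
  A[1:30, 1:30] <- 2
  A[31:60, 31:60] <- 2
  A <- A + diag(3, n)
  cm <- contact_matrix("c", 1e4, A, mask = rep(FALSE, n))
  cm <- kr_balance(cm)
  ins <- insulation_score(cm, square_size = 1e5)
  sc <- ins$score$values
  expect_equal(sort(order(sc)[1:2]), c(30, 31))
})

test_that("flat insulation yields no boundaries", {
  ins <- make_insulation(rep(0, 100))
  expect_warning(ts <- call_boundaries(ins), "single TAD")
  expect_equal(nrow(ts$boundaries), 0)
  expect_equal(nrow(ts$tads), 1)
})

test_that("boundary strength strictly above the noise threshold is required", {
  # single clean insulation valley; measure its strength, then move the
  # threshold onto and just below it
  v <- rep(0, 120)
  v[50:70] <- -seq(0, 1, length.out = 21) * rev(seq(0, 1, length.out = 21)) * 4
  ins <- make_insulation(v)
  free <- call_boundaries(ins, noise_threshold = 0)
  expect_equal(nrow(free$boundaries), 1)
  s0 <- free$boundaries$strength[1]
  at <- suppressWarnings(call_boundaries(ins, noise_threshold = s0))
  expect_equal(nrow(at$boundaries), 0)
  below <- call_boundaries(ins, noise_threshold = s0 - 1e-9)
  expect_equal(nrow(below$boundaries), 1)
})

test_that("candidates near masked bins are dropped by the margin filter", {
  v <- rep(0, 120)
  v[50:70] <- -seq(0, 1, length.out = 21) * rev(seq(0, 1, length.out = 21)) * 4
  mask <- rep(FALSE, 120); mask[62] <- TRUE
  ins <- make_insulation(v, mask = mask)
  with_m <- suppressWarnings(call_boundaries(ins, margin = 3))
  free <- call_boundaries(ins, margin = 0)
  expect_equal(nrow(free$boundaries), 1)
  expect_true(nrow(with_m$boundaries) == 0 ||
                min(abs(with_m$boundaries$bin - 62)) > 3)
})

test_that("planted TAD boundaries are recovered within one bin", {
  cfg <- sim_config(seed = 2, chrom_length = 6e6, tad_size_mean = 6e5)
  sm <- simulate_contact_matrix(cfg, "NT", bin_size = cfg$bin_size_tad)
  ins <- insulation_score(kr_balance(sm$matrix))
  ts <- call_boundaries(ins)
  sc <- score_boundaries(ts$boundaries$pos, sm$truth$tad_boundaries_bp,
                         cfg$bin_size_tad, tol_bins = 1,
                         callable_range = c(7e5, 5.3e6))
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$recall, 0.9)
  # TADs tile between consecutive boundaries, non-overlapping and ordered
  tads <- ts$tads
  expect_true(all(diff(tads$start) > 0))
  expect_true(all(tads$end[-nrow(tads)] <= tads$start[-1]))
})

test_that("boundary calls are invariant to scaling the raw matrix", {
  cfg <- sim_config(seed = 3, chrom_length = 4e6)
  sm <- simulate_contact_matrix(cfg, "NT", bin_size = cfg$bin_size_tad)
  b1 <- call_boundaries(insulation_score(kr_balance(sm$matrix)))
  scaled <- sm$matrix; scaled$raw <- 3 * scaled$raw
  b2 <- call_boundaries(insulation_score(kr_balance(scaled)))
  expect_equal(b1$boundaries$bin, b2$boundaries$bin)
  expect_equal(b1$boundaries$strength, b2$boundaries$strength, tolerance = 1e-6)
})

test_that("TADs overlapping excluded regions are removed", {
  cfg <- sim_config(seed = 3, chrom_length = 4e6)
  sm <- simulate_contact_matrix(cfg, "NT", bin_size = cfg$bin_size_tad)
  ins <- insulation_score(kr_balance(sm$matrix))
  all_t <- call_boundaries(ins)
  excl <- all_t$tads[1, , drop = FALSE]
  some <- call_boundaries(ins, excluded_regions = excl)
  expect_equal(nrow(some$tads), nrow(all_t$tads) - 1)
})

test_that("boundary stability matches a nearest-neighbour oracle, inclusive at the buffer", {
  mk <- function(pos) list(boundaries = data.frame(pos = pos))
  t1 <- mk(c(1e5, 5e5, 9e5))
  expect_equal(boundary_stability(t1, t1)$changed_fraction, 0)
  shifted <- mk(c(1e5 + 2e4, 5e5, 9e5))
  expect_equal(boundary_stability(t1, shifted, buffer = 2e4)$changed_fraction, 0)
  shifted2 <- mk(c(1e5 + 2e4 + 1, 5e5, 9e5))
  expect_equal(boundary_stability(t1, shifted2, buffer = 2e4)$changed_fraction, 1 / 3)
  withr::with_seed(9, {
    for (rep in 1:5) {
      p1 <- sort(sample.int(1e6, 20)); p2 <- sort(sample.int(1e6, 15))
      got <- boundary_stability(mk(p1), mk(p2), buffer = 3e4)
      brute <- vapply(p1, function(p) min(abs(p - p2)) <= 3e4, TRUE)
      expect_equal(got$changed_fraction, mean(!brute))
    }
  })
})

test_that("metaprofiles place boundary features at the profile edges", {
  tads <- genomic_intervals("chrT", c(1e6, 2e6, 3e6), c(1.8e6, 2.9e6, 3.7e6))
  feats <- genomic_intervals("chrT", c(tads$start, tads$end) - 1,
                             c(tads$start, tads$end) + 1)
  prof <- tad_metaprofile(tads, feats, flank = 3.5e4, n_bins = 100)
  # boundaries sit 35 kb into extended TADs of ~800-900 kb: bins 4-5 and 96-97
  inner <- which(prof > 0)
  expect_true(all(inner <= 6 | inner >= 95))
  expect_equal(sum(tad_metaprofile(tads, genomic_intervals(), n_bins = 100)), 0)
})

test_that("uniform features give a flat metaprofile", {
  withr::with_seed(4, {
    starts <- seq(0, 99) * 1e6
    tads <- genomic_intervals("chrT", starts, starts + round(runif(100, 5e5, 9e5)))
    pos <- sort(sample.int(1e8, 20000))
    feats <- genomic_intervals("chrT", pos - 1, pos + 1)
    prof <- tad_metaprofile(tads, feats, n_bins = 50)
    se <- sd(prof) / sqrt(length(prof))
    expect_true(max(abs(prof - mean(prof))) < max(6 * se, 0.3 * mean(prof)))
  })
})

test_that("SNPs on boundaries achieve the minimal empirical P of 1/101", {
  boundaries <- list(boundaries = data.frame(pos = seq(5e5, 9.5e6, by = 5e5)))
  class(boundaries) <- "tad_set"; boundaries$chrom <- "chrT"
  trait <- data.frame(chrom = "chrT", pos = boundaries$boundaries$pos[1:10])
  ctrl <- withr::with_seed(11, lapply(1:100, function(i) {
    data.frame(chrom = "chrT", pos = sample.int(1e7, 10))
  }))
  res <- boundary_distance_test(trait, boundaries, ctrl)
  expect_equal(res$observed_median, 0)
  expect_equal(res$empirical_p, 1 / 101)
})

test_that("a trait set identical to every control set is not significant", {
  boundaries <- list(boundaries = data.frame(pos = c(1e6, 2e6)))
  class(boundaries) <- "tad_set"; boundaries$chrom <- "chrT"
  trait <- data.frame(chrom = "chrT", pos = c(1.2e6, 1.7e6, 2.4e6))
  ctrl <- lapply(1:50, function(i) trait)
  res <- boundary_distance_test(trait, boundaries, ctrl)
  expect_gt(res$empirical_p, 0.5)
  expect_lte(res$empirical_p, 1)
})

test_that("buffered boundaries give zero distance within 10 kb", {
  boundaries <- list(boundaries = data.frame(pos = 1e6))
  class(boundaries) <- "tad_set"; boundaries$chrom <- "chrT"
  trait <- data.frame(chrom = "chrT", pos = c(1e6 + 9999, 1e6 + 10001))
  res <- boundary_distance_test(trait, boundaries,
                                list(data.frame(chrom = "chrT", pos = c(1, 2))))
  expect_equal(res$distances, c(0, 1))
})

test_that("matched sets satisfy base tolerances when the pool copies the trait", {
  trait <- data.frame(snp_id = paste0("t", 1:5), chrom = "chrT",
                      pos = 1:5 * 1e5, maf = seq(0.1, 0.3, length.out = 5),
                      gene_density = 3, dist_nearest_gene = 2e4, n_proxies = 6)
  pool <- do.call(rbind, lapply(1:60, function(k) {
    p <- trait; p$snp_id <- paste0("p", k, "_", 1:5); p$pos <- p$pos + k; p
  }))
  sets <- match_snps(trait, pool, n_sets = 10, seed = 1)
  expect_equal(length(sets), 10)
  for (s in sets) {
    expect_equal(nrow(s), 5)
    expect_true(all(abs(s$maf - trait$maf) <= 0.05 + 1e-12))
    expect_false(any(duplicated(s$snp_id)))
  }
  # deterministic under a fixed seed
  expect_identical(match_snps(trait, pool, n_sets = 3, seed = 7),
                   match_snps(trait, pool, n_sets = 3, seed = 7))
})

test_that("matching capacity and pool-disjointness are enforced", {
  trait <- data.frame(snp_id = "t1", chrom = "c", pos = 1, maf = 0.2,
                      gene_density = 1, dist_nearest_gene = 1e4, n_proxies = 2)
  pool <- do.call(rbind, lapply(1:5, function(k) {
    p <- trait; p$snp_id <- paste0("p", k); p
  }))
  expect_error(match_snps(trait, pool, n_sets = 6), "capacity")
  expect_error(match_snps(trait, rbind(pool, trait), n_sets = 2), "disjoint")
})

test_that("matched control MAF distributions are indistinguishable from the trait", {
  ok <- vapply(1:100, function(seed) {
    withr::with_seed(seed, {
      trait <- data.frame(snp_id = paste0("t", 1:30), chrom = "c", pos = 1:30,
                          maf = runif(30, 0.05, 0.5),
                          gene_density = sample(1:10, 30, TRUE),
                          dist_nearest_gene = runif(30, 1e3, 1e5),
                          n_proxies = rpois(30, 8))
      pool <- data.frame(snp_id = paste0("p", 1:4000), chrom = "c", pos = 1:4000,
                         maf = runif(4000, 0.05, 0.5),
                         gene_density = sample(1:10, 4000, TRUE),
                         dist_nearest_gene = runif(4000, 1e3, 1e5),
                         n_proxies = rpois(4000, 8))
      s <- suppressMessages(match_snps(trait, pool, n_sets = 1, seed = seed))[[1]]
      suppressWarnings(ks.test(s$maf, trait$maf)$p.value) > 0.01
    })
  }, TRUE)
  expect_gte(sum(ok), 95)
})
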