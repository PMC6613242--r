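called_tracks <- function(seed, condition = "NT", ...) {
  cfg <- sim_config(seed = seed, ...)
  sm <- simulate_contact_matrix(cfg, condition)
  list(track = call_compartments(kr_balance(sm$matrix), sm$truth$gene_density),
       truth = sm$truth, cfg = cfg)
}

test_that("planted plaid compartments are recovered bin-by-bin", {
  res <- called_tracks(3)
  truth_lab <- ifelse(res$truth$compartments > 0, "A", "B")
  ok <- !is.na(res$track$labels)
  expect_gte(mean(res$track$labels[ok] == truth_lab[ok]), 0.95)
  # A bins carry positive PC1, B bins negative, and segments partition runs
  expect_true(all((res$track$pc1$values > 0)[res$track$labels == "A"], na.rm = TRUE))
  seg <- res$track$segments
  expect_true(all(seg$id %in% c("A", "B")))
  expect_equal(sum((seg$end - seg$start) / res$cfg$bin_size_compartment), sum(ok))
})

test_that("negating the gene-density track flips every label", {
  cfg <- sim_config(seed = 4)
  sm <- simulate_contact_matrix(cfg, "NT")
  cm <- kr_balance(sm$matrix)
  gd <- sm$truth$gene_density
  ct1 <- call_compartments(cm, gd)
  gd_neg <- binned_track(gd$chrom, gd$bin_size, -gd$values)
  ct2 <- call_compartments(cm, gd_neg)
  ok <- !is.na(ct1$labels)
  expect_true(all(ct1$labels[ok] != ct2$labels[ok]))
})

test_that("pure-decay matrices carry no recoverable compartment signal", {
  cors <- vapply(1:50, function(seed) {
    cfg <- sim_config(seed = seed, compartment_amplitude = 0, chrom_length = 5e6,
                      tad_amplitude = 0, loop_strength = 1)
    sm <- simulate_contact_matrix(cfg, "NT")
    # orient PC1 with a gene-density track independent of the planted
    # labels, so the sign fix cannot leak the truth into the correlation
    gd <- binned_track("chrS", cfg$bin_size_compartment,
                       withr::with_seed(seed + 1000, rpois(sm$matrix$n_bins, 5)))
    ct <- call_compartments(kr_balance(sm$matrix), gd)
    ok <- !is.na(ct$pc1$values)
    suppressWarnings(cor(ct$pc1$values[ok], sm$truth$compartments[ok]))
  }, 0)
  # mean recovered correlation indistinguishable from 0 at alpha = 0.05
  expect_gt(t.test(cors)$p.value, 0.05)
})

test_that("too few unmasked bins yields a masked track with a warning", {
  raw <- matrix(1, 10, 10)
  cm <- contact_matrix("chr1", 5e4, raw, mask = rep(FALSE, 10))
  gd <- binned_track("chr1", 5e4, rep(1, 10))
  expect_warning(ct <- call_compartments(cm, gd), "unmasked")
  expect_true(all(is.na(ct$labels)))
})

test_that("exact PC1 ties inherit the previous unmasked label", {
  cm <- contact_matrix("chr1", 1e4, matrix(1, 6, 6), mask = rep(FALSE, 6))
  ct <- vasculink:::new_compartment_track(cm, c(0, 1, 0, -2, 0, NA))
  expect_equal(ct$labels, c(NA, "A", "A", "B", "B", NA))
})

test_that("identical conditions show no switching and unit PC1 correlation", {
  res <- called_tracks(5)
  sw <- compare_compartments(res$track, res$track)
  expect_equal(nrow(sw$A_to_B), 0)
  expect_equal(nrow(sw$B_to_A), 0)
  expect_equal(sw$genome_fraction_switched, 0)
  expect_equal(sw$pc1_correlation, 1)
})

test_that("fully flipped labels give switched fraction 1", {
  res <- called_tracks(5)
  flip <- res$track
  flip$labels <- chartr("AB", "BA", res$track$labels)
  flip$pc1$values <- -flip$pc1$values
  sw <- compare_compartments(res$track, flip)
  expect_equal(sw$genome_fraction_switched, 1)
})

test_that("the planted switching fraction is recovered within half a percent", {
  cfg <- sim_config(seed = 6, switch_fraction = 0.02)
  nt <- simulate_contact_matrix(cfg, "NT")
  t4 <- simulate_contact_matrix(cfg, "T4")
  c1 <- call_compartments(kr_balance(nt$matrix), nt$truth$gene_density)
  c2 <- call_compartments(kr_balance(t4$matrix), t4$truth$gene_density)
  sw <- compare_compartments(c1, c2)
  expect_lt(abs(sw$genome_fraction_switched - 0.02), 0.005 + 1e-9)
  # switched intervals are A in condition 1 and B in condition 2, bin-wise
  if (nrow(sw$A_to_B) > 0) {
    mid <- floor((sw$A_to_B$start + sw$A_to_B$end) / 2)
    bins <- mid %/% cfg$bin_size_compartment + 1
    expect_true(all(c1$labels[bins] == "A" & c2$labels[bins] == "B"))
  }
})

test_that("bin grid mismatches are rejected", {
  a <- called_tracks(5)$track
  b <- called_tracks(5, chrom_length = 5e6)$track
  expect_error(compare_compartments(a, b), "grid")
})

test_that("the printed class fractions give the reported enrichment ratios", {
  expect_equal(round(enrichment_ratio(0.614, 0.435), 1), 1.4)
  expect_equal(round(enrichment_ratio(0.829, 0.565), 1), 1.5)
  expect_equal(round(enrichment_ratio(0.908, 0.797), 1), 1.1)
  expect_equal(enrichment_ratio(0.3, 0.3), 1)
})

test_that("the binomial tail matches exact enumeration", {
  # k = 9 of n = 10 at p0 = 0.5: P(X >= 9) = 11/1024
  features <- genomic_intervals("chr1", (0:9) * 100, (0:9) * 100 + 50)
  classes <- c(rep("up", 9), "other")
  switches <- genomic_intervals("chr1", 0, 2000)
  background <- rep(c("up", "other"), 500)
  enr <- switching_enrichment(features, classes, switches, "up",
                              background_classes = background)
  expect_equal(enr$k, 9L); expect_equal(enr$n, 10L)
  expect_equal(enr$p_binomial, 11 / 1024, tolerance = 1e-12)
  # exact-summation oracle across n <= 20
  withr::with_seed(1, {
    for (rep in 1:20) {
      n <- sample(1:20, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.1, 0.9)
      upper <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
      got <- pbinom(k - 1, n, p0, lower.tail = FALSE)
      expect_equal(got, upper, tolerance = 1e-10)
    }
  })
})

test_that("class-independent switching has unit enrichment on average", {
  switches <- genomic_intervals("chr1", c(0, 5e5), c(2e5, 8e5))
  enrs <- vapply(1:100, function(seed) {
    withr::with_seed(seed, {
      pos <- sample.int(1e6, 400)
      features <- genomic_intervals("chr1", pos - 1, pos + 1)
      classes <- sample(c("up", "other"), 400, replace = TRUE, prob = c(0.4, 0.6))
      switching_enrichment(features, classes, switches, "up")$enrichment
    })
  }, 0)
  expect_lt(abs(mean(enrs) - 1), 0.05)
})

test_that("an empty switch set flags the enrichment as undefined", {
  features <- genomic_intervals("chr1", 0, 100)
  enr <- switching_enrichment(features, "up", genomic_intervals(), "up")
  expect_true(enr$undefined)
  expect_true(is.na(enr$enrichment))
})
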