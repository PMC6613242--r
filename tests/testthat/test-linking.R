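# A hand-built genome for the linking cascade: 10-kb bins, raw counts set
# directly so loop support is exactly controlled.
link_fixture <- function(n_bins = 100, bin_size = 1e4) {
  raw <- matrix(1, n_bins, n_bins)
  contact_matrix("chrL", bin_size, raw, mask = rep(FALSE, n_bins))
}

test_that("loop support sums raw counts over padded anchor bin pairs", {
  cm <- link_fixture()
  empty <- cm; empty$raw <- matrix(0, cm$n_bins, cm$n_bins)
  a1 <- genomic_intervals("chrL", 100000, 101000)
  a2 <- genomic_intervals("chrL", 500000, 501000)
  expect_equal(count_loop_support(empty, a1, a2), 0)
  # single qualifying bin pair with count 20 and no padding
  one <- empty
  one$raw[11, 51] <- one$raw[51, 11] <- 20
  expect_equal(count_loop_support(one, a1, a2, pad = 0), 20)
  # overlapping padded anchors are undefined
  near <- genomic_intervals("chrL", 103000, 104000)
  expect_message(res <- count_loop_support(cm, a1, near, pad = 5000), "overlap")
  expect_true(is.na(res))
})

test_that("loop support equals a brute-force bin-pair summation", {
  withr::with_seed(6, {
    cm <- link_fixture()
    cm$raw <- matrix(rpois(1e4, 3), 100)
    cm$raw <- cm$raw + t(cm$raw)
    for (rep in 1:10) {
      s1 <- sample.int(7e5, 1); s2 <- s1 + sample(2e4:2e5, 1)
      a1 <- list(start = s1, end = s1 + 800)
      a2 <- list(start = s2, end = s2 + 800)
      pad <- sample(c(0, 5000), 1)
      got <- count_loop_support(cm, a1, a2, pad = pad, quiet = TRUE)
      bins <- function(a) {
        which(vapply(seq_len(100), function(b) {
          (b - 1) * 1e4 < a$end + pad && b * 1e4 > a$start - pad
        }, TRUE))
      }
      i <- bins(a1); j <- bins(a2)
      want <- if (length(intersect(i, j))) NA_real_ else sum(cm$raw[i, j])
      expect_equal(got, want)
    }
  })
})


test_that("exactly the fully-qualifying planted triples pass the cascade", {
  fx <- cascade_fixture()
  links <- build_links(fx$snps, fx$peaks, fx$genes, fx$cm, fx$eqtl, pad = 2000)
  matched <- links[links$snp_id == paste0("rs", substr(links$gene_id, 2, 3)), ]
  expect_equal(nrow(matched), 42)
  expect_equal(sum(links$passes_standard), 12)
  passing <- links[links$passes_standard, ]
  expect_true(all(passing$gene_id == sub("rs", "g", passing$snp_id)))
  expect_setequal(passing$snp_id, fx$snps$snp_id[fx$fail == "none"])
  # each decoy fails exactly its planted filter
  for (k in which(fx$fail != "none")) {
    row <- matched[matched$snp_id == sprintf("rs%02d", k), ]
    flags <- c(support = row$pass_support, expression = row$pass_expression,
               eqtl = row$pass_eqtl)
    expect_equal(names(which(!flags)), unname(fx$fail[k]))
  }
  # every passing record's SNP is inside its peak (re-assertable)
  expect_true(all(passing$peak_start <= fx$snps$pos[match(passing$snp_id, fx$snps$snp_id)] &
                    fx$snps$pos[match(passing$snp_id, fx$snps$snp_id)] < passing$peak_end))
})

test_that("the cascade boundary rules are strict on both sides", {
  fx <- cascade_fixture()
  # support 19 vs 20
  fx2 <- fx
  k19 <- which(fx$fail == "support")[1]
  pi <- (fx$peaks$start[k19]) %/% 1e4 + 1
  gi <- (fx$genes$tss[k19]) %/% 1e4 + 1
  fx2$cm$raw[pi, gi] <- fx2$cm$raw[gi, pi] <- 20
  l2 <- build_links(fx2$snps, fx2$peaks, fx2$genes, fx2$cm, fx2$eqtl, pad = 2000)
  expect_true(l2$pass_support[l2$snp_id == sprintf("rs%02d", k19) &
                                l2$gene_id == sprintf("g%02d", k19)])
  # percentile 9 fails, 10 fails (strict), 11 passes
  fx3 <- fx
  ke <- which(fx$fail == "expression")[1:3]
  fx3$genes$expression_rank_percentile[ke] <- c(9, 10, 11)
  l3 <- build_links(fx3$snps, fx3$peaks, fx3$genes, fx3$cm, fx3$eqtl, pad = 2000)
  got <- l3$pass_expression[match(sprintf("rs%02d g%02d", ke, ke),
                                  paste(l3$snp_id, l3$gene_id))]
  expect_equal(got, c(FALSE, FALSE, TRUE))
  # eQTL P exactly at 1e-3 fails, just below passes
  fx4 <- fx
  kq <- which(fx$fail == "eqtl")[1]
  fx4$eqtl$p[kq] <- 1e-3 - 1e-12
  l4 <- build_links(fx4$snps, fx4$peaks, fx4$genes, fx4$cm, fx4$eqtl, pad = 2000)
  expect_true(l4$pass_eqtl[l4$snp_id == sprintf("rs%02d", kq) &
                             l4$gene_id == sprintf("g%02d", kq)])
})

test_that("passing is the conjunction of the three filters, order-free", {
  fx <- cascade_fixture()
  links <- build_links(fx$snps, fx$peaks, fx$genes, fx$cm, fx$eqtl, pad = 2000)
  expect_equal(links$passes_standard,
               links$pass_support & links$pass_expression & links$pass_eqtl)
})

test_that("stringent passing additionally needs differential features and strong eQTL", {
  fx <- cascade_fixture()
  ok <- fx$snps$snp_id[fx$fail == "none"][1]
  g_ok <- sub("rs", "g", ok)
  fx$eqtl$p[fx$eqtl$snp_id == ok] <- 1e-6
  links <- build_links(fx$snps, fx$peaks, fx$genes, fx$cm, fx$eqtl, pad = 2000,
                       differential_peaks = fx$peaks$id[1],
                       differential_genes = g_ok)
  row <- links[links$snp_id == ok & links$gene_id == g_ok, ]
  expect_true(row$passes_standard && row$passes_stringent)
  other <- links[links$passes_standard & links$snp_id != ok, ]
  expect_true(all(!other$passes_stringent))
})

test_that("a SNP without a sentinel mapping is a panel-integrity error", {
  fx <- cascade_fixture()
  fx$snps$sentinel_id[1] <- NA
  expect_error(build_links(fx$snps, fx$peaks, fx$genes, fx$cm, fx$eqtl),
               "sentinel")
})

test_that("link summaries follow their closed forms and a brute-force recount", {
  links <- data.frame(
    snp_id = c("a", "b", "c"), trait = c("CAD", "CAD", "BP"),
    locus_id = c("L1", "L1", "L2"), gene_id = c("g1", "g2", "g3"),
    distance = c(1e5, 2e5, 5e4),
    passes_standard = c(TRUE, TRUE, FALSE), passes_stringent = FALSE
  )
  s <- summarize_links(links)
  expect_equal(s$n_combinations, 2L)
  expect_equal(unname(s$loci_per_trait["CAD"]), 1L)
  expect_equal(s$distance_mean_bp, 1.5e5)
  expect_equal(s$distance_sd_bp, 5e4) # population SD of {1e5, 2e5}
  one <- summarize_links(links[1, ])
  expect_equal(one$distance_mean_bp, 1e5)
  expect_equal(one$distance_sd_bp, 0)
  none <- summarize_links(links[links$passes_stringent, ])
  expect_equal(none$n_combinations, 0L)
  expect_true(is.na(none$distance_mean_bp))
})
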