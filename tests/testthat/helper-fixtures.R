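# Hand-built genome for the linking-cascade tests: 12 fully-qualifying
# planted (SNP, peak, gene) triples and 30 decoys that each fail exactly
# one filter, with loop support written directly into the raw matrix.

# Build the full cascade fixture: planted triples pass everything, decoys
# each fail exactly one filter.
cascade_fixture <- function() {
  bin <- 1e4
  n_cases <- 42
  cm <- contact_matrix("chrL", bin, matrix(0, 900, 900), mask = rep(FALSE, 900))
  peaks <- NULL; genes <- NULL; snps <- NULL; eqtl <- NULL
  fail <- c(rep("none", 12), rep(c("support", "expression", "eqtl"), each = 10))
  for (k in seq_len(n_cases)) {
    base <- (k - 1) * 2e5 # one isolated locus per 200 kb
    peak <- c(base + 1e4, base + 11e3)
    tss <- base + 1.2e5
    support <- if (fail[k] == "support") 19 else 40
    pct <- if (fail[k] == "expression") 9 else 60
    ep <- if (fail[k] == "eqtl") 1e-3 else 1e-4 # at threshold: excluded
    pi <- peak[1] %/% bin + 1
    gi <- tss %/% bin + 1
    cm$raw[pi, gi] <- cm$raw[gi, pi] <- support
    peaks <- rbind(peaks, data.frame(chrom = "chrL", start = peak[1],
                                     end = peak[2], strand = ".",
                                     id = sprintf("pk%02d", k)))
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("g%02d", k), chrom = "chrL", tss = tss,
      promoter_start = tss - 500, promoter_end = tss + 500,
      expressed = TRUE, expression_rank_percentile = pct))
    snps <- rbind(snps, data.frame(
      snp_id = sprintf("rs%02d", k), chrom = "chrL", pos = peak[1] + 100,
      sentinel_id = sprintf("rs%02d", k),
      trait = rep_len(c("CAD", "BP"), n_cases)[k]))
    eqtl <- rbind(eqtl, data.frame(snp_id = sprintf("rs%02d", k),
                                   gene_id = sprintf("g%02d", k), p = ep))
  }
  class(peaks) <- c("genomic_intervals", "data.frame")
  list(cm = cm, peaks = peaks, genes = genes, snps = snps, eqtl = eqtl,
       fail = fail)
}
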