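#' Simulation configuration
#'
#' Parameters of the synthetic genome emulating the study design: a
#' resting (NT) and TNF-alpha-stimulated (4 h, 24 h) endothelial system
#' with two biological replicates per condition, plaid (checkerboard)
#' compartment structure, block-diagonal TAD enrichment with focal loop
#' peaks, negative-binomial feature counts with planted log10 fold-changes,
#' and SNP panels whose LD proxies cluster around sentinels with
#' exponentially decaying r-squared.
#'
#' @param seed integer; fixes every random draw of a run.
#' @param chrom_length chromosome length in bp.
#' @param bin_size_compartment bin width for compartment-scale matrices
#'   (default 50 kb).
#' @param bin_size_tad bin width for TAD-scale matrices (default 10 kb).
#' @param compartment_block_mean mean compartment block length in bp.
#' @param compartment_amplitude plaid amplitude `a`: same-compartment
#'   contacts scaled by `1 + a`, cross-compartment by `1 - a`.
#' @param switch_fraction fraction of compartment bins whose A/B state
#'   flips between NT and the stimulated conditions (default 0.021,
#'   i.e. 2.1% of the genome).
#' @param tad_size_mean,tad_size_min mean and minimum planted TAD size (bp).
#' @param tad_amplitude within-TAD contact enrichment `t` (same-TAD
#'   contacts scaled by `1 + t`; `t = 1` gives 2x contrast).
#' @param tad_change_fraction fraction of internal TAD boundaries absent
#'   from the stimulated conditions (default 0.077, i.e. 7.7% of
#'   boundaries change on stimulation).
#' @param n_loops number of planted focal loops per condition.
#' @param loop_strength multiplicative contact enrichment at loop anchors.
#' @param depth target total contact count per matrix.
#' @param n_genes,n_peaks feature counts for the count matrices.
#' @param conditions,n_reps condition labels and replicates per condition.
#' @param de_fraction fraction of features with a planted effect.
#' @param lfc_scale magnitude of planted log10 fold-changes.
#' @param nb_dispersion negative-binomial dispersion of feature counts.
#' @param count_mean mean baseline expression/accessibility count.
#' @param n_sentinels_per_trait sentinel SNPs per trait.
#' @param proxies_per_sentinel_mean mean LD proxies per sentinel.
#' @param r2_decay_bp distance scale of LD decay:
#'   `r2 = exp(-distance / r2_decay_bp)`.
#' @param proxy_spread_bp mean physical distance of proxies from their
#'   sentinel (default 50 kb).
#' @param snp_in_peak_fraction fraction of sentinels planted inside
#'   open-chromatin peaks (planted enrichment; 0 = no enrichment).
#' @param n_background_snps size of the non-associated SNP pool carrying
#'   matching attributes, from which matched control sets are drawn.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_length = 1e7,
                       bin_size_compartment = 5e4,
                       bin_size_tad = 1e4,
                       compartment_block_mean = 1.2e6,
                       compartment_amplitude = 0.4,
                       switch_fraction = 0.021,
                       tad_size_mean = 8e5,
                       tad_size_min = 5.5e5,
                       tad_amplitude = 1.0,
                       tad_change_fraction = 0.077,
                       n_loops = 10,
                       loop_strength = 10,
                       depth = 1e6,
                       n_genes = 400,
                       n_peaks = 800,
                       conditions = c("NT", "T4", "T24"),
                       n_reps = 4,
                       de_fraction = 0.1,
                       lfc_scale = 0.5,
                       nb_dispersion = 0.005,
                       count_mean = 5000,
                       n_sentinels_per_trait = 50,
                       proxies_per_sentinel_mean = 10,
                       r2_decay_bp = 5e4,
                       proxy_spread_bp = 5e4,
                       snp_in_peak_fraction = 0.3,
                       n_background_snps = 8000) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == floor(cfg$seed),
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$switch_fraction >= 0, cfg$switch_fraction <= 1,
            cfg$snp_in_peak_fraction >= 0, cfg$snp_in_peak_fraction <= 1,
            cfg$nb_dispersion > 0, cfg$n_reps >= 1,
            cfg$tad_size_min <= cfg$tad_size_mean)
  class(cfg) <- "sim_config"
  cfg
}

# Planted chromosome architecture shared by all conditions: compartment
# blocks (+1 = A, -1 = B), TAD boundaries, loop anchors and the set of
# compartment bins that flip state in stimulated conditions.
plant_architecture <- function(config, bin_size) {
  n_bins <- ceiling(config$chrom_length / bin_size)
  with_seed(derive_seed(config$seed, "architecture"), {
    # compartment blocks: alternating A/B runs on the compartment bin grid,
    # exponential lengths with a floor of at least one TAD so that every
    # compartment edge can coincide with a TAD boundary
    cbs <- config$bin_size_compartment
    min_block <- ceiling(max(2 * cbs, config$tad_size_min) / cbs) * cbs
    lens <- numeric(0)
    while (sum(lens) < config$chrom_length) {
      l <- min_block + rexp(1, rate = 1 / max(config$compartment_block_mean - min_block, 1))
      lens <- c(lens, round(l / cbs) * cbs)
    }
    edges_bp <- pmin(cumsum(lens), config$chrom_length)
    first <- sample(c(-1, 1), 1)
    block_sign <- first * (-1)^(seq_along(edges_bp) - 1)
    # TAD boundaries: every compartment edge is a TAD boundary (A/B
    # transitions fall at domain borders, as in real genomes); blocks are
    # subdivided into TADs of mean tad_size_mean, floor tad_size_min, on
    # the TAD bin grid
    tbs <- config$bin_size_tad
    block_bounds <- c(0, edges_bp)
    tad_edges <- numeric(0)
    for (b in seq_len(length(block_bounds) - 1)) {
      b0 <- block_bounds[b]; b1 <- block_bounds[b + 1]
      cursor <- b0
      while (b1 - cursor >= 2 * config$tad_size_min) {
        size <- config$tad_size_min +
          rexp(1, rate = 1 / max(config$tad_size_mean - config$tad_size_min, 1))
        size <- round(size / tbs) * tbs
        if (b1 - (cursor + size) < config$tad_size_min) break
        cursor <- cursor + size
        tad_edges <- c(tad_edges, cursor)
      }
      if (b1 < config$chrom_length) tad_edges <- c(tad_edges, b1)
    }
    tad_edges <- unique(tad_edges[tad_edges > 0 & tad_edges < config$chrom_length])
    # TAD boundaries dropped in stimulated conditions (adjacent TADs merge);
    # compartment-edge boundaries are kept so compartment switching stays
    # the only compartment-scale difference
    droppable <- setdiff(tad_edges, edges_bp)
    n_drop <- round(config$tad_change_fraction * length(tad_edges))
    tad_dropped <- if (n_drop > 0 && length(droppable) > 0) {
      sample(droppable, min(n_drop, length(droppable)))
    } else numeric(0)
    # switched region: contiguous run of compartment bins, exact bin count
    n_cbin <- ceiling(config$chrom_length / config$bin_size_compartment)
    k_switch <- round(config$switch_fraction * n_cbin)
    if (k_switch > 0) {
      s0 <- sample.int(n_cbin - k_switch + 1, 1)
      switch_cbins <- s0:(s0 + k_switch - 1)
    } else {
      switch_cbins <- integer(0)
    }
    # loop anchors: pairs of TAD-scale bins 100-400 kb apart (typical
    # enhancer-promoter loop distances), placed within one planted TAD as
    # regulatory loops overwhelmingly are
    tad_bounds <- c(0, tad_edges, config$chrom_length)
    gap <- sample(10:40, config$n_loops, replace = TRUE)
    a1_bp <- vapply(gap, function(g) {
      w <- g * tbs
      ok <- which(diff(tad_bounds) >= w + 2 * tbs)
      td <- if (length(ok) == 1) ok else sample(ok, 1)
      lo <- tad_bounds[td]; hi <- tad_bounds[td + 1] - w - tbs
      floor(runif(1, lo, hi) / tbs) * tbs
    }, 0)
    loops_bp <- cbind(a1_bp, a1_bp + gap * tbs)
    dimnames(loops_bp) <- NULL
    list(block_edges_bp = edges_bp, block_sign = block_sign,
         tad_edges_bp = tad_edges, tad_dropped_bp = tad_dropped,
         switch_cbins = switch_cbins,
         loops_bp = loops_bp, n_bins = n_bins)
  })
}

# per-bin compartment sign (+1 A / -1 B) at an arbitrary bin size
compartment_sign_at <- function(arch, config, bin_size, condition) {
  n_bins <- ceiling(config$chrom_length / bin_size)
  mids <- (seq_len(n_bins) - 0.5) * bin_size
  block <- findInterval(mids, c(0, arch$block_edges_bp), rightmost.closed = TRUE)
  sgn <- arch$block_sign[pmin(block, length(arch$block_sign))]
  if (condition != "NT" && length(arch$switch_cbins)) {
    cb <- ceiling(mids / config$bin_size_compartment)
    sgn[cb %in% arch$switch_cbins] <- -sgn[cb %in% arch$switch_cbins]
  }
  sgn
}

#' Simulate a Hi-C contact matrix with planted structure
#'
#' Expected contact between bins i and j is
#' `d(|i-j|) * plaid * tad * loop`, where `d(s) = 1/(1+s)` is the distance
#' decay, the plaid factor is `1 + a` for same-compartment and `1 - a` for
#' cross-compartment bin pairs, the TAD factor is `1 + t` for same-TAD
#' pairs, and planted loop anchor pairs are multiplied by `loop_strength`.
#' Observed counts are Poisson samples scaled to a total of about `depth`;
#' the matrix is exactly symmetric.  Stimulated conditions (`T4`, `T24`)
#' share NT's architecture except for the planted switched compartment
#' bins.
#'
#' @param config a [sim_config()].
#' @param condition condition label (e.g. `"NT"` or `"T4"`).
#' @param bin_size matrix resolution in bp (defaults to the compartment
#'   bin size).
#' @param replicate integer replicate index; replicates share the expected
#'   matrix and differ only in Poisson noise.
#' @return a list with `matrix` (a [contact_matrix()]) and `truth`: planted
#'   per-bin compartment signs (`compartments`), TAD boundary positions in
#'   bp (`tad_boundaries_bp`), loop anchor starts in bp (`loops_bp`), the
#'   switched-bin indices at compartment scale (`switch_cbins`), the
#'   expected (pre-Poisson) matrix and a simulated gene-density track
#'   correlated with the A compartment.
#' @export
simulate_contact_matrix <- function(config, condition = "NT",
                                    bin_size = config$bin_size_compartment,
                                    replicate = 1L) {
  arch <- plant_architecture(config, bin_size)
  n <- ceiling(config$chrom_length / bin_size)
  sgn <- compartment_sign_at(arch, config, bin_size, condition)
  s <- abs(outer(seq_len(n), seq_len(n), `-`))
  expected <- 1 / (1 + s)
  a <- config$compartment_amplitude
  if (a != 0) {
    same <- outer(sgn, sgn, `*`) > 0
    expected <- expected * ifelse(same, 1 + a, 1 - a)
  }
  tad_edges <- arch$tad_edges_bp
  if (condition != "NT") tad_edges <- setdiff(tad_edges, arch$tad_dropped_bp)
  t_amp <- config$tad_amplitude
  if (t_amp != 0) {
    mids <- (seq_len(n) - 0.5) * bin_size
    tad_id <- findInterval(mids, c(0, tad_edges, config$chrom_length))
    expected <- expected * ifelse(outer(tad_id, tad_id, `==`), 1 + t_amp, 1)
  }
  if (config$loop_strength != 1 && nrow(arch$loops_bp) > 0) {
    li <- floor(arch$loops_bp[, 1] / bin_size) + 1
    lj <- floor(arch$loops_bp[, 2] / bin_size) + 1
    ok <- li <= n & lj <= n & li != lj
    expected[cbind(li[ok], lj[ok])] <- expected[cbind(li[ok], lj[ok])] * config$loop_strength
    expected[cbind(lj[ok], li[ok])] <- expected[cbind(lj[ok], li[ok])] * config$loop_strength
  }
  scale <- config$depth / sum(expected[upper.tri(expected, diag = TRUE)])
  expected <- expected * scale
  if (max(expected) < 1) {
    warning("sequencing depth too low to populate the matrix (expected max cell < 1)")
  }
  raw <- matrix(0, n, n)
  ut <- upper.tri(raw, diag = TRUE)
  raw[ut] <- with_seed(
    derive_seed(config$seed, paste("matrix", condition, bin_size, replicate, sep = "_")),
    rpois(sum(ut), expected[ut])
  )
  raw <- raw + t(raw) - diag(diag(raw))
  gene_density <- with_seed(derive_seed(config$seed, paste0("gene_density_", bin_size)),
                            rpois(n, 2 + 8 * (sgn > 0)))
  # simulated matrices carry no coverage bias, so only truly empty bins
  # are masked (no low-coverage quantile rule)
  cm <- contact_matrix("chrS", bin_size, raw)
  list(matrix = cm,
       truth = list(compartments = sgn,
                    tad_boundaries_bp = tad_edges,
                    loops_bp = arch$loops_bp,
                    switch_cbins = arch$switch_cbins,
                    expected = expected,
                    gene_density = binned_track("chrS", bin_size, gene_density)))
}

#' Simulate feature counts with planted log10 fold-changes
#'
#' Counts are negative-binomial with per-sample library-size factors; a
#' `de_fraction` of features receive a planted log10 fold-change of
#' magnitude `lfc_scale` (random sign) in the stimulated conditions (T4
#' and/or T24, mirroring an early/late/sustained response).
#'
#' @param config a [sim_config()].
#' @param n_features number of features (defaults to `config$n_genes`).
#' @param feature_prefix id prefix (e.g. `"gene"` or `"peak"`).
#' @return list with `counts` (matrix, features x samples, sample names
#'   `COND_rep`), `samples` (data.frame of condition/replicate),
#'   `size_factors_true`, and `truth`: per-feature true log10 fold-change
#'   for each of the three condition comparisons.
#' @export
simulate_counts <- function(config, n_features = config$n_genes,
                            feature_prefix = "feat") {
  conds <- config$conditions
  with_seed(derive_seed(config$seed, paste0("counts_", feature_prefix)), {
    base <- rlnorm(n_features, log(config$count_mean), 1)
    n_de <- round(config$de_fraction * n_features)
    de_idx <- if (n_de > 0) sample.int(n_features, n_de) else integer(0)
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    # response pattern: 1 = early (T4 only), 2 = late (T24 only), 3 = sustained
    pattern <- if (n_de > 0) sample(1:3, n_de, replace = TRUE) else integer(0)
    lfc <- matrix(0, n_features, length(conds),
                  dimnames = list(NULL, conds))
    if (n_de > 0) {
      lfc[de_idx, "T4"] <- ifelse(pattern != 2, sign * config$lfc_scale, 0)
      lfc[de_idx, "T24"] <- ifelse(pattern != 1, sign * config$lfc_scale, 0)
    }
    samples <- expand.grid(replicate = seq_len(config$n_reps),
                           condition = conds, stringsAsFactors = FALSE)[, 2:1]
    sf <- runif(nrow(samples), 0.7, 1.3)
    counts <- matrix(0L, n_features, nrow(samples))
    for (k in seq_len(nrow(samples))) {
      mu <- base * 10^lfc[, samples$condition[k]] * sf[k]
      counts[, k] <- rnbinom(n_features, mu = mu, size = 1 / config$nb_dispersion)
    }
    ids <- sprintf("%s%04d", feature_prefix, seq_len(n_features))
    rownames(counts) <- ids
    colnames(counts) <- paste0(samples$condition, "_", samples$replicate)
    truth <- data.frame(
      feature_id = ids,
      lfc_NT_vs_T4 = lfc[, "T4"],
      lfc_NT_vs_T24 = lfc[, "T24"],
      lfc_T4_vs_T24 = lfc[, "T24"] - lfc[, "T4"],
      stringsAsFactors = FALSE
    )
    list(counts = counts, samples = samples, size_factors_true = sf,
         truth = truth)
  })
}

#' Simulate peaks, genes, a SNP panel and an eQTL table
#'
#' Open-chromatin peaks are placed uniformly (non-overlapping), genes get
#' TSS/promoter coordinates and expression ranks, sentinel SNPs are placed
#' uniformly with a planted fraction inside peaks, LD proxies scatter
#' around their sentinel with `r2 = exp(-distance / r2_decay_bp)`, and the
#' eQTL table assigns small P values to SNP-gene pairs whose peak and
#' promoter fall on planted loop anchors (plus uniform-P decoy pairs).
#'
#' @param config a [sim_config()].
#' @param truth architecture truth from [simulate_contact_matrix()] (used to
#'   anchor eQTL pairs on planted loops); may be `NULL` for a loop-free
#'   panel.
#' @return list with `peaks` ([genomic_intervals()]), `genes` (data.frame
#'   with gene_id, tss, promoter_start/end, expressed, expression_rank_percentile),
#'   `panel` (SNP table: snp_id, chrom, pos, type, sentinel_id, r2, trait,
#'   maf, gene_density, dist_nearest_gene, n_proxies), `eqtl`
#'   (snp_id, gene_id, p), `background` (non-associated SNPs with the
#'   same attribute columns, the pool for matched-control drawing) and
#'   `planted_links` (the ground-truth SNP-peak-gene combinations placed
#'   on loop anchors, `NULL` when no loop truth is supplied).
#' @export
simulate_snp_panel <- function(config, truth = NULL) {
  L <- config$chrom_length
  chrom <- "chrS"
  with_seed(derive_seed(config$seed, "snp_panel"), {
    # peaks: uniform starts on a 200-bp grid, width 200-1500 bp, merged
    starts <- sort(sample.int(floor(L / 200) - 10, config$n_peaks)) * 200
    widths <- round(runif(config$n_peaks, 200, 1500))
    peaks <- merge_intervals(genomic_intervals(chrom, starts, pmin(starts + widths, L)))
    peaks$id <- sprintf("peak%05d", seq_len(nrow(peaks)))
    # genes: TSS uniform, promoter +/- 500 bp, expression percentile uniform
    tss <- sort(sample.int(L - 2000, config$n_genes) + 1000)
    expressed <- runif(config$n_genes) > 0.1
    pct <- rep(NA_real_, config$n_genes)
    pct[expressed] <- rank(runif(sum(expressed))) / sum(expressed) * 100
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
      chrom = chrom, tss = tss, strand = sample(c("+", "-"), config$n_genes, TRUE),
      promoter_start = pmax(tss - 500, 0), promoter_end = tss + 500,
      expressed = expressed, expression_rank_percentile = pct,
      stringsAsFactors = FALSE
    )
    # planted SNP-peak-gene-loop links: for each planted loop, an
    # open-chromatin peak over anchor 1 holding a disease sentinel, and a
    # well-expressed gene whose promoter sits on anchor 2
    planted_links <- NULL
    if (!is.null(truth) && nrow(truth$loops_bp) > 0) {
      nl <- nrow(truth$loops_bp)
      a1 <- truth$loops_bp[, 1]; a2 <- truth$loops_bp[, 2]
      link_peaks <- genomic_intervals(chrom, pmax(a1 - 300, 0), a1 + 700)
      peaks <- merge_intervals(rbind(peaks[, 1:5], link_peaks))
      gidx <- seq_len(nl) # repurpose the first nl genes as loop targets
      genes$tss[gidx] <- a2 + 200
      genes$promoter_start[gidx] <- pmax(a2 - 300, 0)
      genes$promoter_end[gidx] <- a2 + 700
      genes$expressed[gidx] <- TRUE
      genes$expression_rank_percentile[gidx] <- round(runif(nl, 50, 99), 2)
      genes <- genes[order(genes$tss), , drop = FALSE]
      rownames(genes) <- NULL
      planted_links <- data.frame(
        snp_id = sprintf("rsLNK%02d", seq_len(nl)), chrom = chrom,
        # distinct positions even when two loops share an anchor bin
        pos = a1 + 200 + seq_len(nl) - 1, trait = rep_len(c("CAD", "BP"), nl),
        gene_id = sprintf("gene%04d", gidx),
        anchor1 = a1, anchor2 = a2, stringsAsFactors = FALSE
      )
    }
    peaks$id <- sprintf("peak%05d", seq_len(nrow(peaks)))
    # sentinels per trait; a planted fraction of the disease (CAD/BP)
    # sentinels falls inside peaks, while BMI is a non-vascular control
    # trait left unenriched
    traits <- c("CAD", "BP", "BMI")
    panel <- do.call(rbind, lapply(traits, function(tr) {
      ns <- config$n_sentinels_per_trait
      frac <- if (tr == "BMI") 0 else config$snp_in_peak_fraction
      n_in <- round(frac * ns)
      pos <- sample.int(L, ns)
      if (n_in > 0 && nrow(peaks) > 0) {
        pk <- peaks[sample.int(nrow(peaks), n_in, replace = TRUE), ]
        pos[seq_len(n_in)] <- floor(pk$start + runif(n_in) * (pk$end - pk$start))
      }
      sid <- sprintf("rs%s%04d", tr, seq_len(ns))
      sent <- data.frame(snp_id = sid, chrom = chrom, pos = pos,
                         type = "sentinel", sentinel_id = sid, r2 = 1,
                         trait = tr, stringsAsFactors = FALSE)
      if (tr != "BMI" && !is.null(planted_links)) {
        pl <- planted_links[planted_links$trait == tr, ]
        if (nrow(pl)) {
          sent <- rbind(sent, data.frame(
            snp_id = pl$snp_id, chrom = chrom, pos = pl$pos,
            type = "sentinel", sentinel_id = pl$snp_id, trait = tr, r2 = 1,
            stringsAsFactors = FALSE))
        }
      }
      np <- rpois(nrow(sent), config$proxies_per_sentinel_mean)
      sent$n_proxies <- np
      prox <- do.call(rbind, lapply(seq_len(nrow(sent)), function(i) {
        if (np[i] == 0) return(NULL)
        d <- round(rexp(np[i], 1 / config$proxy_spread_bp) + 1) * sample(c(-1, 1), np[i], TRUE)
        data.frame(snp_id = paste0(sent$snp_id[i], "_p", seq_len(np[i])),
                   chrom = chrom,
                   pos = pmin(pmax(sent$pos[i] + d, 0), L - 1), type = "proxy",
                   sentinel_id = sent$snp_id[i],
                   r2 = exp(-abs(d) / config$r2_decay_bp),
                   trait = tr, n_proxies = np[i], stringsAsFactors = FALSE)
      }))
      rbind(sent, prox)
    }))
    # matching attributes
    panel$maf <- round(runif(nrow(panel), 0.05, 0.5), 4)
    panel <- cbind(panel, gene_attrs(panel$pos, genes$tss))
    rownames(panel) <- NULL
    # non-associated background pool with the same attribute columns
    nb <- config$n_background_snps
    background <- data.frame(
      snp_id = sprintf("rsBG%05d", seq_len(nb)), chrom = chrom,
      pos = sample.int(L, nb), type = "background",
      sentinel_id = NA_character_, r2 = NA_real_, trait = "none",
      n_proxies = rpois(nb, config$proxies_per_sentinel_mean),
      maf = round(runif(nb, 0.05, 0.5), 4), stringsAsFactors = FALSE
    )
    background <- cbind(background, gene_attrs(background$pos, genes$tss))
    # eQTL table: strong P for SNP-gene pairs on planted loop anchors
    eqtl <- NULL
    if (!is.null(truth) && nrow(truth$loops_bp) > 0) {
      anchor_w <- 2e4
      hits <- lapply(seq_len(nrow(truth$loops_bp)), function(k) {
        a1 <- truth$loops_bp[k, 1]; a2 <- truth$loops_bp[k, 2]
        sn <- panel$snp_id[abs(panel$pos - a1) < anchor_w | abs(panel$pos - a2) < anchor_w]
        gn <- genes$gene_id[abs(genes$tss - a1) < anchor_w | abs(genes$tss - a2) < anchor_w]
        if (length(sn) && length(gn)) expand.grid(snp_id = sn, gene_id = gn,
                                                  stringsAsFactors = FALSE)
        else NULL
      })
      eqtl <- unique(do.call(rbind, hits))
      if (!is.null(eqtl) && nrow(eqtl)) {
        eqtl$p <- 10^runif(nrow(eqtl), -8, -4)
      }
    }
    n_decoy <- 5 * config$n_genes
    decoy <- data.frame(
      snp_id = panel$snp_id[sample.int(nrow(panel), n_decoy, replace = TRUE)],
      gene_id = genes$gene_id[sample.int(nrow(genes), n_decoy, replace = TRUE)],
      p = runif(n_decoy), stringsAsFactors = FALSE
    )
    eqtl <- unique(rbind(eqtl, decoy))
    rownames(eqtl) <- NULL
    list(peaks = peaks, genes = genes, panel = panel, eqtl = eqtl,
         background = background, planted_links = planted_links)
  })
}

# distance to nearest TSS and gene count within +/- 500 kb, via sorted TSS
gene_attrs <- function(pos, tss, density_window = 5e5) {
  st <- sort(tss)
  idx <- findInterval(pos, st)
  left <- ifelse(idx >= 1, pos - st[pmax(idx, 1)], Inf)
  right <- ifelse(idx < length(st), st[pmin(idx + 1, length(st))] - pos, Inf)
  data.frame(
    dist_nearest_gene = pmin(left, right),
    gene_density = findInterval(pos + density_window, st) -
      findInterval(pos - density_window, st)
  )
}
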