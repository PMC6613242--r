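#' Pipeline run configuration
#'
#' Collects every stage threshold in one place, with the study's values as
#' defaults: FDR < 0.001 and |log10 FC| > 0.3 for differential
#' classification, r2 > 0.8 for LD proxy expansion, >= 20 Hi-C reads of
#' loop support, bottom-10-percentile expression exclusion, eQTL P < 1e-3
#' (standard) and < 1e-5 (stringent), 50-kb compartment and 10-kb TAD
#' matrix resolutions, 500-kb insulation square, 200-kb delta span, 0.1
#' noise threshold, 3-bin boundary margin, 10-kb boundary-overlap and
#' 20-kb boundary-stability buffers, 35-kb metaprofile flank, 100 matched
#' SNP sets and 1000 circular shifts.
#'
#' @param sim a [sim_config()]; its seed drives every stage.
#' @param ... named overrides of any parameter listed above (see
#'   `formals(run_config)`).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       fdr_threshold = 0.001, lfc_threshold = 0.3,
                       r2_threshold = 0.8,
                       support_min = 20, expr_pct_min = 10,
                       eqtl_p_max = 1e-3, stringent_eqtl_p_max = 1e-5,
                       loop_pad = 5000,
                       square_size = 5e5, delta_span = 2e5,
                       noise_threshold = 0.1, boundary_margin = 3,
                       stability_buffer = 2e4, boundary_buffer = 1e4,
                       metaprofile_flank = 3.5e4,
                       n_matched_sets = 100, n_shifts = 1000,
                       kr_tol = 1e-6, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown run_config parameter(s): ", paste(names(extra), collapse = ", "))
  }
  cfg <- as.list(environment())
  cfg$extra <- NULL
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> differential -> balance -> compartments -> tads ->
#' enrich -> link in dependency order, writing per-stage artifacts and a
#' manifest to `out_dir`.  All randomness derives from the simulation
#' seed via stage-keyed seeds, so a rerun with the same configuration
#' reproduces every output byte-exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  manifest <- list()
  note <- function(stage, artifact, n) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, artifact = artifact, n_rows = n, stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  res$simulate <- stage("simulate", {
    comp <- lapply(c(NT = "NT", T4 = "T4"), function(cond) {
      reps <- lapply(1:2, function(r) {
        simulate_contact_matrix(sim, cond, sim$bin_size_compartment, replicate = r)
      })
      list(pooled = pool_replicates(lapply(reps, `[[`, "matrix")),
           reps = lapply(reps, `[[`, "matrix"), truth = reps[[1]]$truth)
    })
    tadm <- lapply(c(NT = "NT", T4 = "T4"), function(cond) {
      sim1 <- simulate_contact_matrix(sim, cond, sim$bin_size_tad, replicate = 1)
      list(matrix = sim1$matrix, truth = sim1$truth)
    })
    gene_counts <- simulate_counts(sim, sim$n_genes, "gene")
    peak_counts <- simulate_counts(sim, sim$n_peaks, "peak")
    aux <- simulate_snp_panel(sim, truth = tadm$NT$truth)
    write_bed(aux$peaks, file.path(out_dir, "peaks.bed"))
    write.table(aux$panel, file.path(out_dir, "snp_panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(aux$eqtl, file.path(out_dir, "eqtl.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(aux$genes, file.path(out_dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(feature_id = rownames(gene_counts$counts), gene_counts$counts),
                file.path(out_dir, "counts_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(feature_id = rownames(peak_counts$counts), peak_counts$counts),
                file.path(out_dir, "counts_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix(comp$NT$pooled, file.path(out_dir, "matrix_comp_NT.coo"))
    write_matrix(comp$T4$pooled, file.path(out_dir, "matrix_comp_T4.coo"))
    note("simulate", "peaks.bed", nrow(aux$peaks))
    note("simulate", "snp_panel.tsv", nrow(aux$panel))
    note("simulate", "counts_genes.tsv", nrow(gene_counts$counts))
    list(comp = comp, tadm = tadm, gene_counts = gene_counts,
         peak_counts = peak_counts, aux = aux)
  })

  res$differential <- stage("differential", {
    comparisons <- list(c("NT", "T4"), c("NT", "T24"), c("T4", "T24"))
    run_tables <- function(cc) {
      tabs <- lapply(comparisons, function(cmp) {
        test_differential(cc$counts, cc$samples, cmp,
                          fdr_threshold = config$fdr_threshold,
                          lfc_threshold = config$lfc_threshold)
      })
      list(tables = tabs, union = union_differential(tabs))
    }
    genes <- run_tables(res$simulate$gene_counts)
    peaks <- run_tables(res$simulate$peak_counts)
    gt <- do.call(rbind, genes$tables); pt <- do.call(rbind, peaks$tables)
    write.table(gt, file.path(out_dir, "differential_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pt, file.path(out_dir, "differential_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("differential", "differential_genes.tsv", nrow(gt))
    note("differential", "differential_peaks.tsv", nrow(pt))
    list(genes = genes, peaks = peaks)
  })

  res$balance <- stage("balance", {
    out <- list(
      comp_NT = kr_balance(res$simulate$comp$NT$pooled, tol = config$kr_tol),
      comp_T4 = kr_balance(res$simulate$comp$T4$pooled, tol = config$kr_tol),
      tad_NT = kr_balance(res$simulate$tadm$NT$matrix, tol = config$kr_tol),
      tad_T4 = kr_balance(res$simulate$tadm$T4$matrix, tol = config$kr_tol)
    )
    note("balance", "matrices", 4L)
    out
  })

  res$compartments <- stage("compartments", {
    gd <- res$simulate$comp$NT$truth$gene_density
    ct <- lapply(res$balance[c("comp_NT", "comp_T4")], call_compartments,
                 gene_density = gd)
    names(ct) <- c("NT", "T4")
    write_bedgraph(ct$NT$pc1, file.path(out_dir, "pc1_NT.bedgraph"))
    write_bedgraph(ct$T4$pc1, file.path(out_dir, "pc1_T4.bedgraph"))
    switches <- compare_compartments(ct$NT, ct$T4)
    # enrichment of up genes in B-to-A and down genes in A-to-B compartments
    dg <- res$differential$genes$tables[[1]] # NT vs T4
    gtab <- res$simulate$aux$genes
    gi <- genomic_intervals(gtab$chrom, pmax(gtab$tss - 1, 0), gtab$tss + 1)
    gcls <- dg$class[match(gtab$gene_id, dg$feature_id)]
    enr <- list(
      up_B_to_A = switching_enrichment(gi, gcls, switches$B_to_A, "up"),
      down_A_to_B = switching_enrichment(gi, gcls, switches$A_to_B, "down")
    )
    enr_df <- do.call(rbind, lapply(names(enr), function(nm) {
      e <- enr[[nm]]
      data.frame(test = nm, k = e$k, n = e$n, p0 = e$p0,
                 enrichment = e$enrichment, p_binomial = e$p_binomial)
    }))
    write.table(enr_df, file.path(out_dir, "switch_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sw <- rbind(
      if (nrow(switches$A_to_B)) cbind(switches$A_to_B, direction = "A_to_B"),
      if (nrow(switches$B_to_A)) cbind(switches$B_to_A, direction = "B_to_A")
    )
    if (is.null(sw)) {
      sw <- cbind(genomic_intervals(), direction = character(0))
    }
    write.table(sw, file.path(out_dir, "switch_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("compartments", "switch_regions.tsv", nrow(sw))
    list(tracks = ct, switches = switches, enrichment = enr)
  })

  res$tads <- stage("tads", {
    ins <- lapply(res$balance[c("tad_NT", "tad_T4")], insulation_score,
                  square_size = config$square_size)
    tads <- lapply(ins, call_boundaries, delta_span = config$delta_span,
                   noise_threshold = config$noise_threshold,
                   margin = config$boundary_margin)
    names(ins) <- names(tads) <- c("NT", "T4")
    write_bedgraph(ins$NT$normalized, file.path(out_dir, "insulation_NT.bedgraph"))
    write.table(tads$NT$boundaries, file.path(out_dir, "boundaries_NT.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(tads$NT$tads, file.path(out_dir, "tads_NT.bed"))
    stability <- boundary_stability(tads$NT, tads$T4, buffer = config$stability_buffer)
    profile <- tad_metaprofile(tads$NT, res$simulate$aux$peaks,
                               flank = config$metaprofile_flank)
    write.table(data.frame(bin = seq_along(profile), density_per_kb = profile),
                file.path(out_dir, "tad_metaprofile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    panel <- res$simulate$aux$panel
    trait_sent <- panel[panel$type == "sentinel" & panel$trait == "CAD", ]
    pool <- res$simulate$aux$background
    dist_test <- NULL
    if (!is.null(pool) && config$n_matched_sets * nrow(trait_sent) <= nrow(pool)) {
      sets <- match_snps(trait_sent, pool, n_sets = config$n_matched_sets,
                         seed = derive_seed(sim$seed, "match_snps"))
      dist_test <- boundary_distance_test(trait_sent, tads$NT, sets,
                                          buffer = config$boundary_buffer)
      write.table(data.frame(observed_median = dist_test$observed_median,
                             control_median = median(dist_test$control_medians),
                             empirical_p = dist_test$empirical_p),
                  file.path(out_dir, "boundary_distance_test.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    note("tads", "boundaries_NT.tsv", nrow(tads$NT$boundaries))
    list(insulation = ins, tads = tads, stability = stability,
         metaprofile = profile, dist_test = dist_test)
  })

  res$enrich <- stage("enrich", {
    panel <- res$simulate$aux$panel
    peaks <- res$simulate$aux$peaks
    chrom_lengths <- setNames(sim$chrom_length, "chrS")
    per_trait <- lapply(c(CAD = "CAD", BP = "BP", BMI = "BMI"), function(tr) {
      snps <- expand_ld(panel, config$r2_threshold, trait = tr)
      frac <- peak_snp_fraction(peaks, snps)
      sig <- enrichment_significance(peaks, snps, chrom_lengths,
                                     n_shifts = config$n_shifts,
                                     seed = derive_seed(sim$seed, paste0("shift_", tr)))
      data.frame(trait = tr, n_snps = nrow(snps), n_peaks = frac$n_peaks,
                 n_peaks_with_snp = frac$n_peaks_with_snp,
                 fraction = frac$fraction, observed = sig$observed,
                 null_mean = sig$null_mean, null_sd = sig$null_sd,
                 empirical_p = sig$empirical_p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per_trait)
    rownames(tab) <- NULL
    write.table(tab, file.path(out_dir, "snp_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("enrich", "snp_enrichment.tsv", nrow(tab))
    tab
  })

  res$link <- stage("link", {
    panel <- res$simulate$aux$panel
    snps <- expand_ld(panel, config$r2_threshold, trait = c("CAD", "BP"))
    links <- build_links(
      snps, res$simulate$aux$peaks, res$simulate$aux$genes,
      res$simulate$tadm$NT$matrix, res$simulate$aux$eqtl,
      support_min = config$support_min, expr_pct_min = config$expr_pct_min,
      eqtl_p_max = config$eqtl_p_max,
      stringent_eqtl_p_max = config$stringent_eqtl_p_max,
      pad = config$loop_pad,
      differential_peaks = res$differential$peaks$union$features,
      differential_genes = res$differential$genes$union$features
    )
    write.table(links, file.path(out_dir, "links.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary <- summarize_links(links)
    note("link", "links.tsv", nrow(links))
    list(links = links, summary = summary)
  })

  mf <- do.call(rbind, manifest)
  mf <- rbind(mf, data.frame(stage = "run", artifact = paste0("seed=", sim$seed),
                             n_rows = NA_integer_))
  write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}
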