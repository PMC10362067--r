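#' Default pipeline run configuration
#'
#' All thresholds default to the analysis' canonical values: MAF >= 0.05,
#' >= 40 genotyped individuals, HWE exact p >= 1e-6, family-wise alpha 0.05
#' with perfect-LD (r-squared = 1) collapsing, conditional strata of at
#' least 50 individuals, clique pruning at edge weight >= 3 (i.e. "more
#' than 2" shared variants), repertoire QC at >= 100 reads per isotype and
#' >= 200 clones, GWAS cut p < 4e-6, and 4 ASD quantile bins.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides for any config entry (nested lists are merged
#'   shallowly).
#' @return A nested configuration list.
#' @export
default_run_config <- function(out_dir = "ighqtl_run", seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed, isotype = "IgM",
    simulate = list(enabled = TRUE, n_samples = 150, model = NULL,
                    n_clones = NULL),
    inputs = list(vcf = NULL, airr = NULL, covariates = NULL,
                  features_bed = NULL, gwas_tsv = NULL,
                  allele_genotypes = NULL),
    thresholds = list(maf_min = 0.05, min_genotyped = 40, hwe_min = 1e-6,
                      alpha = 0.05, min_stratum_n = 50, ld_collapse_r2 = 1.0,
                      clique_min_weight = 3, min_clones = 200, min_reads = 100,
                      gwas_p_max = 4e-6, asd_bins = 4),
    dosage_policy = "haploid-doubled", impute_policy = "drop",
    verbose = TRUE)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

pipeline_stages <- function() {
  c("simulate", "filter", "usage", "guqtl", "conditional", "network",
    "enrich", "similarity", "allele_assoc")
}

#' Run the end-to-end gene-usage QTL pipeline
#'
#' Executes (optionally) simulate, then filter, usage, guqtl, conditional,
#' network, enrich, similarity and allele-assoc; every stage writes TSV/CSV
#' artifacts under `out_dir` and the run closes with a machine-readable
#' JSON manifest (seeds, thresholds, per-stage record counts). A stage
#' failure aborts with a stage-named error; artifacts of completed stages
#' are retained.
#'
#' @param config list from [default_run_config()] (or a YAML path in the
#'   same shape).
#' @param stages subset of stages to run (default all).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = pipeline_stages()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  manifest <- list(seed = config$seed, isotype = config$isotype,
                   thresholds = th, stages = list())
  state <- new.env(parent = emptyenv())
  started <- Sys.time()

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    msg(sprintf("[%s] running...", name), verbose = config$verbose)
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- c(list(status = "complete",
                                       seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
                                  res$counts %||% list())
    state[[name]] <- res
    invisible(res)
  }

  run_stage("simulate", function() {
    model <- config$simulate$model
    if (is.null(model)) model <- default_locus_model()
    if (is.character(model)) model <- read_locus_model(model)
    cohort <- simulate_cohort(model, n_samples = config$simulate$n_samples,
                              seed = config$seed,
                              n_clones = config$simulate$n_clones,
                              isotype = config$isotype)
    paths <- write_cohort(cohort, file.path(out, "cohort"))
    feats <- simulate_features(model, seed = config$seed)
    write_bed(feats, file.path(out, "cohort", "features.bed"))
    gw <- simulate_gwas_table(model, seed = config$seed)
    data.table::fwrite(gw, file.path(out, "cohort", "gwas.tsv"), sep = "\t")
    config$inputs$vcf <<- paths$vcf
    config$inputs$airr <<- paths$airr_dir
    config$inputs$covariates <<- paths$covariates
    config$inputs$features_bed <<- file.path(out, "cohort", "features.bed")
    config$inputs$gwas_tsv <<- file.path(out, "cohort", "gwas.tsv")
    config$inputs$allele_genotypes <<- paths$alleles
    list(cohort = cohort,
         counts = list(n_samples = nrow(cohort$samples),
                       n_clones = nrow(cohort$clones)))
  })

  run_stage("filter", function() {
    gm <- read_vcf(config$inputs$vcf)
    gm <- impute_missing(gm, policy = config$impute_policy, seed = config$seed)
    fc <- filter_common(gm, maf_min = th$maf_min,
                        min_genotyped = th$min_genotyped, hwe_min = th$hwe_min)
    data.table::fwrite(fc$matrix$variants, file.path(out, "variants_retained.tsv"),
                       sep = "\t")
    data.table::fwrite(fc$log, file.path(out, "variants_removed.tsv"), sep = "\t")
    list(gm_all = gm, gm = fc$matrix,
         counts = list(n_variants_in = nrow(gm$variants),
                       n_variants_retained = nrow(fc$matrix$variants)))
  })

  run_stage("usage", function() {
    airr <- config$inputs$airr
    files <- if (dir.exists(airr)) list.files(airr, "\\.tsv$", full.names = TRUE)
             else airr
    clones <- data.table::rbindlist(lapply(files, read_airr))
    qc <- qc_filter(clones, min_reads = th$min_reads,
                    min_clones = th$min_clones)
    data.table::fwrite(qc, file.path(out, "qc_log.tsv"), sep = "\t")
    keep <- qc$sample_id[qc$keep & qc$isotype == config$isotype]
    clones <- clones[clones$sample_id %in% keep]
    deleted <- deleted_genes_from_genotypes(state$filter$gm_all)
    counts <- count_clones(clones, deleted_genes = deleted)
    covs <- read_covariates(config$inputs$covariates)
    um <- usage_fractions(counts, covariates = covs)
    data.table::fwrite(data.table::as.data.table(um$U, keep.rownames = "gene"),
                       file.path(out, "usage_fractions.csv"))
    list(usage = um, clones = clones,
         counts = list(n_samples = length(um$samples), n_genes = nrow(um$U)))
  })

  run_stage("guqtl", function() {
    fit <- run_guqtl(state$usage$usage, state$filter$gm,
                     alpha = th$alpha, ld_collapse_r2 = th$ld_collapse_r2,
                     dosage_policy = config$dosage_policy)
    data.table::fwrite(fit$results, file.path(out, "guqtl_results.tsv"), sep = "\t")
    data.table::fwrite(fit$summaries, file.path(out, "guqtl_summaries.tsv"),
                       sep = "\t")
    list(fit = fit,
         counts = list(n_tests = nrow(fit$results),
                       effective_tests = fit$effective_tests,
                       threshold = fit$threshold,
                       n_significant_pairs = sum(fit$results$significant),
                       n_genes_with_lead = sum(fit$summaries$lead_significant)))
  })

  run_stage("conditional", function() {
    cond <- run_conditional(state$guqtl$fit, state$usage$usage,
                            state$filter$gm,
                            min_stratum_n = th$min_stratum_n, alpha = th$alpha,
                            maf_min = th$maf_min,
                            min_genotyped = th$min_genotyped,
                            hwe_min = th$hwe_min)
    if (nrow(cond$summary))
      data.table::fwrite(cond$summary, file.path(out, "conditional_guqtls.tsv"),
                         sep = "\t")
    list(cond = cond,
         counts = list(n_genes_scanned = length(cond$scans),
                       n_secondary = nrow(cond$summary)))
  })

  run_stage("network", function() {
    sig <- state$guqtl$fit$results[significant == TRUE, .(gene, variant)]
    graph <- build_gene_graph(sig)
    data.table::fwrite(graph$edges, file.path(out, "gene_graph_edges.tsv"),
                       sep = "\t")
    data.table::fwrite(graph$variant_gene_counts,
                       file.path(out, "variant_gene_counts.tsv"), sep = "\t")
    cl <- find_gene_cliques(graph, min_weight = th$clique_min_weight)
    data.table::fwrite(cl$table, file.path(out, "gene_cliques.tsv"), sep = "\t")
    list(graph = graph, cliques = cl,
         counts = list(n_nodes = length(graph$nodes),
                       n_edges = nrow(graph$edges),
                       n_cliques = length(cl$cliques)))
  })

  run_stage("enrich", function() {
    fit <- state$guqtl$fit
    gm <- state$filter$gm
    snv <- gm$variants$id[gm$variants$class == "SNV"]
    tested <- fit$results[!is.na(gate_p), unique(variant)]
    sig_v <- fit$results[significant == TRUE, unique(variant)]
    guqtl_snvs <- intersect(sig_v, snv)
    bg_snvs <- setdiff(intersect(tested, snv), sig_v)
    res <- NULL
    if (!is.null(config$inputs$features_bed) && length(guqtl_snvs) &&
        length(bg_snvs)) {
      feats <- read_bed_features(config$inputs$features_bed)
      pos <- stats::setNames(gm$variants$position, gm$variants$id)
      memb <- overlap_variants(pos[c(guqtl_snvs, bg_snvs)], feats)
      res <- fisher_enrichment(guqtl_snvs, bg_snvs, memb)
      data.table::fwrite(res, file.path(out, "feature_enrichment.tsv"),
                         sep = "\t")
    }
    gwres <- NULL
    if (!is.null(config$inputs$gwas_tsv) && length(sig_v)) {
      gw <- read_gwas_table(config$inputs$gwas_tsv)
      pos <- stats::setNames(gm$variants$position, gm$variants$id)
      gwres <- gwas_overlap(sig_v, pos, gw, p_max = th$gwas_p_max)
      data.table::fwrite(gwres, file.path(out, "gwas_overlap.tsv"), sep = "\t")
    }
    list(enrichment = res, gwas = gwres,
         counts = list(n_guqtl_snvs = length(guqtl_snvs),
                       n_background_snvs = length(bg_snvs),
                       n_gwas_overlaps = if (is.null(gwres)) 0L else nrow(gwres)))
  })

  run_stage("similarity", function() {
    fit <- state$guqtl$fit
    gm <- state$filter$gm[fit$samples, ]
    um <- state$usage$usage
    corr <- pairwise_usage_correlation(
      structure(list(U = um$U[, fit$samples, drop = FALSE]),
                class = "usage_matrix", names = "U"))
    sets <- list(
      lead_guqtls = unique(fit$summaries$lead_variant[fit$summaries$lead_significant]),
      all_guqtls = fit$results[significant == TRUE, unique(variant)])
    rows <- list()
    results <- list()
    for (nm in names(sets)) {
      vs <- intersect(sets[[nm]], gm$variants$id[gm$variants$n_alleles == 2])
      if (length(vs) < 1) next
      D <- asd_matrix(gm, vs)
      sim <- compare_asd_groups(D, corr, n_bins = th$asd_bins)
      results[[nm]] <- sim
      rows[[nm]] <- data.table::data.table(
        set = nm, sim$bin_summary,
        ks_p = sim$ks$p, low_bin_mean = sim$low_bin_mean,
        high_bin_mean = sim$high_bin_mean)
    }
    if (length(rows))
      data.table::fwrite(data.table::rbindlist(rows),
                         file.path(out, "asd_similarity.tsv"), sep = "\t")
    list(similarity = results,
         counts = list(n_sets = length(results)))
  })

  run_stage("allele_assoc", function() {
    res <- list()
    if (!is.null(config$inputs$allele_genotypes)) {
      ag <- data.table::fread(config$inputs$allele_genotypes, sep = "\t")
      fit <- state$guqtl$fit
      gm <- state$filter$gm[fit$samples, ]
      labs <- genotype_labels(gm)
      mm <- default_merge_map()
      for (g in unique(ag$gene)) {
        gg <- if (g %in% names(mm)) mm[[g]] else g
        srow <- fit$summaries[gene == gg & lead_significant == TRUE]
        if (!nrow(srow)) next
        lead <- srow$lead_variant
        gv <- stats::setNames(labs[, lead], gm$samples)
        tab <- tryCatch(allele_guqtl_table(ag[ag$gene == g], gv),
                        error = function(e) NULL)
        if (is.null(tab)) next
        p <- fisher_assoc(tab, seed = config$seed)
        res[[g]] <- data.table::data.table(
          gene = g, lead_variant = lead, p = as.numeric(p),
          method = attr(p, "method"),
          n = sum(tab))
      }
      if (length(res))
        data.table::fwrite(data.table::rbindlist(res),
                           file.path(out, "allele_guqtl_assoc.tsv"), sep = "\t")
    }
    list(assoc = if (length(res)) data.table::rbindlist(res) else NULL,
         counts = list(n_genes_tested = length(res)))
  })

  manifest$package_version <- as.character(utils::packageVersion("ighqtl"))
  manifest$elapsed_seconds <- round(as.numeric(Sys.time() - started, units = "secs"), 2)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(as.list(state), list(manifest = manifest, config = config)))
}
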