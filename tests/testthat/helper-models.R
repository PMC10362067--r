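# Small fast locus models and memoised default-cohort runs shared across
# test files.

tiny_model <- function(noise_sd = 0.2) {
  genes <- data.frame(
    name = c("IGHJ4", "IGHJ6", "IGHD3-3", "IGHD4-4", "IGHD3-9",
             "IGHV1-2", "IGHV3-23", "IGHV3-23D", "IGHV3-66"),
    segment = c("J", "J", "D", "D", "D", "V", "V", "V", "V"),
    position = c(2000L, 3000L, 20000L, 24000L, 28000L,
                 100000L, 140000L, 144000L, 180000L),
    functional = TRUE, stringsAsFactors = FALSE)
  sv <- list(
    id = "DEL1", span = c(19000L, 25000L),
    alleles = data.frame(name = c("REF", "DEL"), freq = c(0.7, 0.3)),
    copy_map = list(REF = c("IGHD3-3" = 1, "IGHD4-4" = 1),
                    DEL = c("IGHD3-3" = 0, "IGHD4-4" = 0)),
    deleted_ranges = list(DEL = list(c(19000L, 25000L))))
  blocks <- data.frame(block = 1:4, hap_freq = c(0.5, 0.3, 0.6, 0.45))
  snvs <- data.frame(
    id = sprintf("s%02d", 1:12),
    position = c(19200L, 19400L, 19600L,                 # inside the deletion
                 50000L, 50200L, 50400L,
                 90000L, 90200L, 90400L,
                 181000L, 181200L, 181400L),
    block = rep(1:4, each = 3),
    on_hapA = rep(TRUE, 12),
    containing_sv = c(rep("DEL1", 3), rep(NA_character_, 9)),
    stringsAsFactors = FALSE)
  effects <- data.frame(variant = "s10", gene = "IGHV3-66", multiplier = 1.8)
  bw <- stats::setNames(c(1, 1.5, 0.8, 1.2, 1.0, 2.0, 1.4, 1.4, 0.9),
                        genes$name)
  locus_model(genes = genes, svs = list(DEL1 = sv), blocks = blocks,
              snvs = snvs, effects = effects, baseline_weights = bw,
              coding_alleles = data.frame(
                gene = "IGHV3-66", tag_snv = "s10",
                ref_label = "*03", alt_label = "*01",
                stringsAsFactors = FALSE),
              noise_sd = noise_sd)
}

# single-block model used for LD / frequency checks
one_block_model <- function(n_snvs = 3, hap_freq = 0.4) {
  genes <- data.frame(name = c("IGHV1-2", "IGHJ4"), segment = c("V", "J"),
                      position = c(50000L, 2000L), functional = TRUE)
  locus_model(
    genes = genes,
    blocks = data.frame(block = 1L, hap_freq = hap_freq),
    snvs = data.frame(id = sprintf("s%02d", seq_len(n_snvs)),
                      position = 10000L + seq_len(n_snvs) * 100L,
                      block = 1L, on_hapA = TRUE,
                      containing_sv = NA_character_),
    baseline_weights = c("IGHV1-2" = 1, "IGHJ4" = 1),
    noise_sd = 0)
}

.acc_env <- new.env(parent = emptyenv())

acc_model <- function() {
  if (is.null(.acc_env$model)) .acc_env$model <- default_locus_model()
  .acc_env$model
}

# One full default-cohort analysis at a seed, reduced to the small summaries
# the acceptance checks need (memoised so several criteria share the runs).
run_default_seed <- function(seed) {
  key <- paste0("seed_", seed)
  if (!is.null(.acc_env[[key]])) return(.acc_env[[key]])
  m <- acc_model()
  co <- simulate_cohort(m, 150, seed = seed)
  gm <- as_genotype_matrix(co)
  fc <- filter_common(gm)
  um <- usage_fractions(
    count_clones(co$clones,
                 deleted_genes = deleted_genes_from_genotypes(gm)),
    covariates = co$samples)
  fit <- run_guqtl(um, fc$matrix)
  D <- dosage_matrix(fc$matrix)

  # merged true usage probabilities per sample for a merged gene name
  mm <- default_merge_map()
  true_prob <- function(gene) {
    raw <- c(gene, names(mm)[mm == gene])
    p <- 0
    for (seg in names(co$truth$usage_probs)) {
      pm <- co$truth$usage_probs[[seg]]
      hit <- intersect(raw, colnames(pm))
      if (length(hit)) p <- p + rowSums(pm[, hit, drop = FALSE])
    }
    p
  }
  cd <- data.frame(sample_id = co$samples$sample_id, age = co$samples$age,
                   platform = factor(co$samples$platform))
  truth_r2 <- function(gene, causal) {
    x <- D[, causal]
    y <- true_prob(gene)
    df <- data.frame(y = y, x = x, age = cd$age, platform = cd$platform)
    df <- df[stats::complete.cases(df), ]
    full <- summary(stats::lm(y ~ x + age + platform, df))$adj.r.squared
    cov <- summary(stats::lm(y ~ age + platform, df))$adj.r.squared
    full - cov
  }

  tl <- co$truth$expected_leads
  tl <- tl[tl$causal_type != "SNV_secondary", ]
  lead_rows <- lapply(seq_len(nrow(tl)), function(i) {
    g <- tl$gene[i]
    srow <- fit$summaries[which(fit$summaries[["gene"]] == g), ]
    leads <- strsplit(srow$lead_variants, ",")[[1]]
    ok <- tl$causal_variant[i] %in% leads
    if (!ok) {
      r2s <- vapply(leads, function(v) {
        ld <- tryCatch(compute_ld(fc$matrix, v, tl$causal_variant[i]),
                       error = function(e) list(r2 = NA_real_))
        ld$r2 %||% NA_real_
      }, 0)
      ok <- any(!is.na(r2s) & r2s >= 1 - 1e-9)
    }
    r2t <- if (tl$causal_type[i] == "SV" &&
                 fit$summaries$lead_class[match(g, fit$summaries$gene)] == "MSV")
      NA_real_ else truth_r2(g, tl$causal_variant[i])
    data.frame(gene = g, causal = tl$causal_variant[i], lead_ok = ok,
               lead_r2 = srow$lead_r2_adj, truth_r2 = r2t,
               stringsAsFactors = FALSE)
  })
  leads <- do.call(rbind, lead_rows)

  # conditional scan on the gene with the planted secondary effect
  cond <- conditional_scan(fit, "IGHD3-3", um, fc$matrix)
  sec_blocks <- m$snvs$block[match(m$effects$variant[m$effects$gene == "IGHD3-3"],
                                   m$snvs$id)]
  sec_ids <- m$snvs$id[m$snvs$block %in% sec_blocks]
  cond_found <- FALSE
  for (st in cond$strata) {
    if (is.null(st$results)) next
    sig <- st$results$variant[st$results$significant]
    if (any(sig %in% sec_ids)) cond_found <- TRUE
  }

  # copy-number series for the merged duplication entity
  cn <- co$truth$copy_number[, "IGHV3-23"] + co$truth$copy_number[, "IGHV3-23D"]
  u <- um$U["IGHV3-23", co$samples$sample_id]
  grp <- split(u, cn)
  cn_means <- vapply(grp, mean, 0)
  cn_se <- vapply(grp, function(x) stats::sd(x) / sqrt(length(x)), 0)
  cn_true_means <- vapply(split(true_prob("IGHV3-23"), cn), mean, 0)

  res <- list(leads = leads, cond_found = cond_found,
              cond_skipped = cond$skipped,
              cn_means = cn_means, cn_se = cn_se,
              cn_true_means = cn_true_means,
              n_sig_genes = sum(fit$summaries$lead_significant))
  .acc_env[[key]] <- res
  res
}
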