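# Association engine -----------------------------------------------------
#
# The scan fits, for every gene x variant pair, the linear model
#   usage ~ dosage + age + platform
# and (for SNV/COMPLEX_SV/MSV classes) the ANOVA model with genotype as a
# categorical factor after the same covariates. Covariate projections are
# shared across variants with the same used-sample mask, and per-variant
# statistics are computed for all genes at once, so a full cohort scan is a
# handful of matrix products per variant.

# build the covariate design matrix (intercept always present)
covariate_design <- function(covariates, samples) {
  if (is.null(covariates)) {
    return(matrix(1, length(samples), 1,
                  dimnames = list(samples, "(Intercept)")))
  }
  cv <- as.data.frame(covariates)
  cv <- cv[match(samples, cv$sample_id), , drop = FALSE]
  if (anyNA(cv$sample_id)) stopf("covariates missing for some samples")
  terms <- c()
  if ("age" %in% names(cv) && length(unique(cv$age)) > 1) terms <- c(terms, "age")
  if ("platform" %in% names(cv)) {
    cv$platform <- droplevels(factor(cv$platform))
    if (nlevels(cv$platform) > 1) terms <- c(terms, "platform")
  }
  f <- if (length(terms)) stats::reformulate(terms) else ~1
  X <- stats::model.matrix(f, cv)
  rownames(X) <- samples
  X
}

# per-mask cache entry: orthonormal covariate basis and residualised usage
mask_cache_entry <- function(Y, C, rows) {
  Cu <- C[rows, , drop = FALSE]
  keep <- qr(Cu)$rank
  Qc <- qr.Q(qr(Cu))[, seq_len(keep), drop = FALSE]
  Yu <- Y[rows, , drop = FALSE]
  Yres <- Yu - Qc %*% crossprod(Qc, Yu)
  ybar <- colMeans(Yu)
  tss <- colSums(Yu^2) - nrow(Yu) * ybar^2
  list(Qc = Qc, Yu = Yu, Yres = Yres, rss_cov = colSums(Yres^2), tss = tss,
       k = ncol(Qc), n = nrow(Yu))
}

adj_r2 <- function(r2, n, q) 1 - (1 - r2) * (n - 1) / (n - 1 - q)

# fit one variant against all genes; returns a list of per-gene vectors
fit_variant <- function(ce, x, labs, biallelic, do_anova) {
  n <- ce$n; k <- ce$k; G <- ncol(ce$Yu)
  na <- rep(NA_real_, G)
  out <- list(p_lm = na, beta = na, r2_adj = na, p_anova = na,
              fold_change = na, n_used = n)
  cls <- sort(unique(labs))
  Z <- outer(labs, cls, `==`) * 1
  sizes <- colSums(Z)
  means <- crossprod(Z, ce$Yu) / sizes           # class x gene usage means
  out$group_labels <- cls
  out$group_sizes <- sizes
  out$group_means <- means

  if (biallelic && stats::var(x) > 0 && n - k - 1 >= 1) {
    xres <- x - ce$Qc %*% crossprod(ce$Qc, x)
    xx <- sum(xres^2)
    if (xx > 1e-12) {
      xy <- crossprod(xres, ce$Yres)[1, ]
      beta <- xy / xx
      rss_full <- pmax(ce$rss_cov - xy^2 / xx, 0)
      df <- n - k - 1
      se2 <- rss_full / df / xx
      tstat <- ifelse(se2 > 0, beta / sqrt(se2), Inf)
      tstat[rss_full <= .Machine$double.eps * ce$tss & beta == 0] <- 0
      out$p_lm <- clamp_p(2 * stats::pt(-abs(tstat), df))
      out$p_lm[beta == 0 & rss_full == ce$rss_cov] <- 1
      out$beta <- beta
      r2_cov <- 1 - ce$rss_cov / ce$tss
      r2_full <- 1 - rss_full / ce$tss
      out$r2_adj <- adj_r2(r2_full, n, k) - adj_r2(r2_cov, n, k - 1)
    }
  }
  if (do_anova && length(cls) >= 2 && n - k - (length(cls) - 1) >= 1) {
    Zr <- Z[, -1, drop = FALSE]
    Zres <- Zr - ce$Qc %*% crossprod(ce$Qc, Zr)
    qz <- qr(Zres)
    r <- qz$rank
    if (r >= 1) {
      Qz <- qr.Q(qz)[, seq_len(r), drop = FALSE]
      proj <- crossprod(Qz, ce$Yres)
      drop_ss <- colSums(proj^2)
      rss_full <- pmax(ce$rss_cov - drop_ss, 0)
      df2 <- n - k - r
      fstat <- (drop_ss / r) / (rss_full / df2)
      out$p_anova <- clamp_p(stats::pf(fstat, r, df2, lower.tail = FALSE))
      if (!biallelic) {
        r2_cov <- 1 - ce$rss_cov / ce$tss
        r2_full <- 1 - rss_full / ce$tss
        out$r2_adj <- adj_r2(r2_full, n, k - 1 + r) - adj_r2(r2_cov, n, k - 1)
      }
    }
  }
  # fold change between homozygote-equivalent groups (hemizygotes count as
  # full-dosage homozygotes under the haploid-doubled policy)
  if (biallelic) {
    g0 <- which(cls %in% c("0/0", "0")); g2 <- which(cls %in% c("1/1", "1"))
    if (length(g0) && length(g2)) {
      m0 <- colSums(means[g0, , drop = FALSE] * sizes[g0]) / sum(sizes[g0])
      m2 <- colSums(means[g2, , drop = FALSE] * sizes[g2]) / sum(sizes[g2])
      lo <- pmin(m0, m2); hi <- pmax(m0, m2)
      out$fold_change <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, NA_real_))
    }
  } else {
    homs <- grep("^(\\d+)/\\1$|^\\d+$", cls)
    if (length(homs) >= 2) {
      mh <- means[homs, , drop = FALSE]
      lo <- apply(mh, 2, min); hi <- apply(mh, 2, max)
      out$fold_change <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, NA_real_))
    }
  }
  out
}

# full scan: every gene x variant pair
guqtl_scan <- function(usage, gm, covariates = NULL,
                       dosage_policy = "haploid-doubled",
                       anova_classes = c("SNV", "COMPLEX_SV", "MSV"),
                       min_class_n = 3) {
  samples <- intersect(usage$samples, gm$samples)
  if (!length(samples)) stopf("no overlapping samples between usage and genotypes")
  gm <- gm[samples, ]
  Y <- t(usage$U[, samples, drop = FALSE])
  C <- covariate_design(covariates %||% usage$covariates, samples)
  D <- dosage_matrix(gm, policy = dosage_policy)
  LAB <- genotype_labels(gm)
  genes <- colnames(Y)
  nv <- nrow(gm$variants)
  cache <- new.env(parent = emptyenv())
  get_ce <- function(rows) {
    key <- paste(which(rows), collapse = ",")
    ce <- cache[[key]]
    if (is.null(ce)) {
      ce <- mask_cache_entry(Y, C, rows)
      if (length(ls(cache)) < 12) cache[[key]] <- ce
    }
    ce
  }
  res <- vector("list", nv)
  for (j in seq_len(nv)) {
    vid <- gm$variants$id[j]
    vclass <- gm$variants$class[j]
    biallelic <- gm$variants$n_alleles[j] == 2
    labs <- LAB[, j]
    ok <- !is.na(labs)
    tb <- table(labs[ok])
    keep_cls <- names(tb)[tb >= min_class_n]
    used <- ok & labs %in% keep_cls
    nu <- sum(used)
    base <- data.table::data.table(
      variant = vid, gene = genes, class = vclass, position = gm$variants$position[j])
    if (length(keep_cls) < 2 || nu < 3) {
      base[, `:=`(n_used = nu, p_lm = NA_real_, p_anova = NA_real_,
                  beta = NA_real_, r2_adj = NA_real_, fold_change = NA_real_,
                  group_means = NA_character_, group_sizes = NA_character_,
                  note = "constant_genotype")]
      res[[j]] <- base
      next
    }
    ce <- get_ce(used)
    x <- if (biallelic) D[used, j] else rep(0, nu)
    fit <- fit_variant(ce, x, labs[used], biallelic,
                       do_anova = vclass %in% anova_classes)
    gm_str <- apply(round(fit$group_means, 8), 2, function(m)
      paste(fit$group_labels, m, sep = "=", collapse = "|"))
    gs_str <- paste(fit$group_labels, fit$group_sizes, sep = "=", collapse = "|")
    base[, `:=`(n_used = fit$n_used, p_lm = fit$p_lm, p_anova = fit$p_anova,
                beta = fit$beta, r2_adj = fit$r2_adj,
                fold_change = fit$fold_change,
                group_means = gm_str, group_sizes = gs_str,
                note = NA_character_)]
    res[[j]] <- base
  }
  out <- data.table::rbindlist(res)
  # significance gate: linear-regression p for biallelic variants,
  # ANOVA p for multi-allelic ones (which have no dosage encoding)
  out[, gate_p := data.table::fifelse(is.na(p_lm), p_anova, p_lm)]
  out
}

#' Test one gene-variant association
#'
#' Fits `usage ~ dosage + age + platform` (linear regression) and, for
#' SNV/complex-SV/multi-allelic-SV classes, the ANOVA model with genotype as
#' a categorical factor after the same covariates, on pairwise-complete
#' samples. Genotype classes carrying fewer than `min_class_n` samples are
#' dropped from the test and from fold-change groups. Hemizygous calls are
#' dosage-encoded by the haploid-doubled policy (single allele = full
#' dosage).
#'
#' @param y named numeric vector of usage fractions (names = sample ids).
#' @param a1,a2 allele-index vectors for the variant (NA `a2` = hemizygous;
#'   both NA = missing), aligned with `y`'s names.
#' @param covariates optional data.frame (`sample_id`, `age`, `platform`).
#' @param var_class variant class string (default "SNV").
#' @param min_class_n genotype classes smaller than this are dropped.
#' @return List with `p_lm`, `p_anova`, `beta`, `r2_adj` (adjusted R-squared
#'   gained by the genotype term over the covariate-only model),
#'   `fold_change` (larger/smaller homozygote-group mean), `group_means`,
#'   `group_sizes`, `n_used` and `note` (e.g. "constant_genotype").
#' @export
associate <- function(y, a1, a2, covariates = NULL, var_class = "SNV",
                      min_class_n = 3) {
  samples <- names(y) %||% sprintf("S%04d", seq_along(y))
  n_all <- if (var_class == "SNV") 2L else max(c(a1, a2, 1L), na.rm = TRUE) + 1L
  vdf <- data.frame(id = "v", position = 1L, class = var_class,
                    alleles = paste(c("ref", paste0("alt", seq_len(n_all - 1))),
                                    collapse = ","))
  gmat <- genotype_matrix(vdf, matrix(as.integer(a1), ncol = 1),
                          matrix(as.integer(a2), ncol = 1), samples = samples)
  um <- structure(list(U = matrix(y, nrow = 1,
                                  dimnames = list("gene", samples)),
                       segment = c(gene = "V"), samples = samples,
                       covariates = covariates),
                  class = "usage_matrix")
  row <- guqtl_scan(um, gmat, covariates = covariates,
                    min_class_n = min_class_n)
  if (identical(row$note[1], "constant_genotype"))
    warning("constant genotype vector; association skipped")
  as.list(row[1])
}

#' Bonferroni threshold over effective (LD-collapsed) tests
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param effective_tests number of effective tests, i.e. perfect-LD variant
#'   groups counted once (see [collapse_perfect_ld()]).
#' @return `alpha / effective_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, effective_tests) {
  if (effective_tests < 1) stopf("effective_tests must be >= 1")
  alpha / effective_tests
}

#' Run the gene-usage QTL scan
#'
#' Tests every retained gene against every filtered common variant.
#' Significance is gated on the linear-regression p-value for biallelic
#' variants and on the ANOVA p-value for multi-allelic variants; the
#' threshold is `alpha` divided by the number of perfect-LD variant groups
#' (one global threshold, matching per-gene Bonferroni with an identical
#' variant set per gene). Per-gene summaries report the lead variant(s) (all
#' tied at the minimum p, ties preserved), the lead p, class, adjusted
#' R-squared and fold change.
#'
#' @param usage a `usage_matrix` (QC-passed samples).
#' @param gm a filtered `genotype_matrix`.
#' @param covariates optional covariate table (defaults to the one attached
#'   to `usage`).
#' @param alpha family-wise alpha (default 0.05).
#' @param ld_collapse_r2 r-squared treated as perfect LD (default 1).
#' @param dosage_policy hemizygote encoding (see [encode_dosage()]).
#' @param per_gene_correction if TRUE, each gene's significance threshold
#'   counts only LD groups testable for that gene; default FALSE (global).
#' @return An object of class `guqtl_result`: list with `results` (full
#'   gene x variant table), `summaries` (per-gene), `threshold`,
#'   `effective_tests`, `ld`, `alpha` and `samples`.
#' @export
run_guqtl <- function(usage, gm, covariates = NULL, alpha = 0.05,
                      ld_collapse_r2 = 1, dosage_policy = "haploid-doubled",
                      per_gene_correction = FALSE) {
  samples <- intersect(usage$samples, gm$samples)
  if (!length(samples)) stopf("no overlapping samples")
  gms <- gm[samples, ]
  results <- guqtl_scan(usage, gms, covariates = covariates,
                        dosage_policy = dosage_policy)
  ld <- collapse_perfect_ld(gms, r2_threshold = ld_collapse_r2,
                            policy = dosage_policy)
  thr <- bonferroni_threshold(alpha, ld$effective_tests)
  results[, significant := !is.na(gate_p) & gate_p < thr]
  if (per_gene_correction) {
    eff_g <- results[!is.na(gate_p),
                     .(eff = data.table::uniqueN(ld$group_of[variant])),
                     by = gene]
    results <- merge(results, eff_g, by = "gene", all.x = TRUE)
    results[, significant := !is.na(gate_p) & gate_p < alpha / eff]
    results[, eff := NULL]
  }
  summaries <- results[!is.na(gate_p), {
    mp <- min(gate_p)
    tie <- gate_p <= mp * (1 + 1e-9)
    lead_idx <- which(tie)[order(position[tie])]
    .(n_significant = sum(significant),
      lead_variants = paste(variant[lead_idx], collapse = ","),
      lead_variant = variant[lead_idx][1],
      lead_p = mp, lead_class = class[lead_idx][1],
      lead_r2_adj = r2_adj[lead_idx][1],
      lead_fold_change = fold_change[lead_idx][1],
      lead_significant = significant[lead_idx][1])
  }, by = gene]
  structure(list(results = results, summaries = summaries, threshold = thr,
                 effective_tests = ld$effective_tests, ld = ld, alpha = alpha,
                 samples = samples, dosage_policy = dosage_policy),
            class = "guqtl_result")
}

#' @export
print.guqtl_result <- function(x, ...) {
  cat(sprintf(paste0("<guqtl_result> %d genes x %d variants, %d samples\n",
                     "  effective tests: %d, threshold: %.3g\n",
                     "  genes with a significant lead: %d; significant pairs: %d\n"),
              data.table::uniqueN(x$results$gene),
              data.table::uniqueN(x$results$variant), length(x$samples),
              x$effective_tests, x$threshold,
              sum(x$summaries$lead_significant),
              sum(x$results$significant)))
  invisible(x)
}

#' Conditional scan within homozygous strata of the lead variant
#'
#' For a gene with a significant lead, re-runs the association within the
#' individuals homozygous for the lead's reference allele and (separately)
#' its alternate allele. Each stratum with at least `min_stratum_n` samples
#' is re-filtered with the same common-variant rules (MAF, genotyped count,
#' HWE), perfect-LD groups and the Bonferroni threshold are recomputed
#' within the stratum, and every remaining variant is tested against the
#' gene's usage. Strata below `min_stratum_n` are skipped and logged. The
#' left-most co-lead (by locus position) anchors stratification.
#'
#' @param fit a `guqtl_result`.
#' @param gene gene to condition on.
#' @param usage,gm,covariates the inputs used for `fit`.
#' @param min_stratum_n minimum homozygous-stratum size (default 50).
#' @param alpha family-wise alpha within the stratum.
#' @param maf_min,min_genotyped,hwe_min stratum re-filter thresholds.
#' @return List with one entry per tested stratum (`results`, `threshold`,
#'   `effective_tests`, `n`) plus `skipped` (strata below the size rule) and
#'   `lead_variant`.
#' @export
conditional_scan <- function(fit, gene, usage, gm, covariates = NULL,
                             min_stratum_n = 50, alpha = 0.05,
                             maf_min = 0.05, min_genotyped = 40,
                             hwe_min = 1e-6) {
  stopifnot(inherits(fit, "guqtl_result"))
  idx <- which(fit$summaries[["gene"]] == gene)
  srow <- as.data.frame(fit$summaries)[idx, , drop = FALSE]
  if (!nrow(srow)) stopf("gene '%s' not in scan summaries", gene)
  lead <- srow$lead_variant
  gms <- gm[fit$samples, ]
  j <- match(lead, gms$variants$id)
  labs <- genotype_labels(gms)[, j]
  d <- dosage_matrix(gms)[, j]
  biallelic <- gms$variants$n_alleles[j] == 2
  strata <- if (biallelic) {
    list(ref_hom = !is.na(d) & d == 0, alt_hom = !is.na(d) & d == 2)
  } else {
    homs <- grep("^(\\d+)/\\1$", unique(labs[!is.na(labs)]), value = TRUE)
    stats::setNames(lapply(homs, function(h) !is.na(labs) & labs == h),
                    paste0("hom_", sub("/.*", "", homs)))
  }
  out <- list(lead_variant = lead, gene = gene, strata = list(),
              skipped = data.frame(stratum = character(), n = integer()))
  for (snm in names(strata)) {
    rows <- which(strata[[snm]])
    if (length(rows) < min_stratum_n) {
      out$skipped <- rbind(out$skipped,
                           data.frame(stratum = snm, n = length(rows)))
      next
    }
    ids <- fit$samples[rows]
    gm_s <- gms[ids, ]
    fc <- filter_common(gm_s, maf_min = maf_min,
                        min_genotyped = min(min_genotyped, length(ids)),
                        hwe_min = hwe_min)
    if (!nrow(fc$matrix$variants)) {
      out$strata[[snm]] <- list(results = NULL, n = length(ids),
                                note = "no_polymorphic_variants")
      next
    }
    u_s <- usage
    u_s$U <- usage$U[, ids, drop = FALSE]
    u_s$C <- usage$C[, ids, drop = FALSE]
    u_s$samples <- ids
    if (!is.null(u_s$covariates))
      u_s$covariates <- u_s$covariates[u_s$covariates$sample_id %in% ids, ]
    u_s$U <- u_s$U[gene, , drop = FALSE]
    u_s$C <- u_s$C[gene, , drop = FALSE]
    u_s$segment <- usage$segment[gene]
    res <- guqtl_scan(u_s, fc$matrix, covariates = covariates)
    ld <- collapse_perfect_ld(fc$matrix)
    thr <- bonferroni_threshold(alpha, ld$effective_tests)
    res[, significant := !is.na(gate_p) & gate_p < thr]
    out$strata[[snm]] <- list(results = res, threshold = thr,
                              effective_tests = ld$effective_tests,
                              n = length(ids))
  }
  out
}

#' Conditional scans for all genes with a significant lead
#'
#' @param fit a `guqtl_result`.
#' @param usage,gm,covariates the inputs used for `fit`.
#' @param ... passed to [conditional_scan()].
#' @return List keyed by gene; each element as in [conditional_scan()], plus
#'   a `summary` data.table of significant secondary variants.
#' @export
run_conditional <- function(fit, usage, gm, covariates = NULL, ...) {
  genes <- fit$summaries$gene[fit$summaries$lead_significant]
  scans <- lapply(genes, function(g)
    conditional_scan(fit, g, usage, gm, covariates = covariates, ...))
  names(scans) <- genes
  rows <- list()
  for (g in genes) {
    for (snm in names(scans[[g]]$strata)) {
      st <- scans[[g]]$strata[[snm]]
      if (is.null(st$results)) next
      sig <- st$results[significant == TRUE]
      if (nrow(sig)) {
        sig <- data.table::copy(sig)[, `:=`(stratum = snm, cond_gene = g,
                                            lead_variant = scans[[g]]$lead_variant)]
        rows[[paste(g, snm)]] <- sig
      }
    }
  }
  list(scans = scans,
       summary = if (length(rows)) data.table::rbindlist(rows)
                 else data.table::data.table())
}
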