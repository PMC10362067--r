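#' Simulate cohort haplotypes, genotypes and covariates
#'
#' Draws `n_samples` diploid individuals from a [locus_model()]. SNV alleles
#' are drawn per LD block from a two-haplotype pool (so segregating SNVs
#' within a block are in perfect LD and SNVs in different blocks are
#' independent), SV alleles are drawn per stated frequencies, and SNVs whose
#' position is removed by a deletion allele on a haplotype are absent from
#' that haplotype: one deleted haplotype yields a hemizygous genotype call,
#' two yield a missing call. Also draws age, sequencing platform and the
#' per-sample lognormal usage-noise factors consumed by
#' [simulate_usage_probs()].
#'
#' @param model a validated `locus_model`.
#' @param n_samples number of individuals (>= 2).
#' @param seed master seed; per-stage child seeds are derived from it by
#'   fixed offsets.
#' @return An object of class `sim_cohort` (genotypes only; attach
#'   repertoires with [simulate_clones()] or use [simulate_cohort()]).
#' @export
simulate_haplotypes <- function(model, n_samples, seed) {
  validate_locus_model(model)
  if (n_samples < 2) stopf("n_samples must be >= 2")
  n <- as.integer(n_samples)
  genes <- model$genes$name
  snvs <- model$snvs
  ns <- nrow(snvs)

  samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
  cov <- model$covariate_model
  with_seed(child_seed(seed, "covariates"), {
    samples$age <- round(stats::runif(n, cov$age_range[1], cov$age_range[2]))
    samples$platform <- sample(cov$platforms, n, replace = TRUE,
                               prob = cov$platform_probs)
  })

  sv_hap <- list()
  hap1 <- hap2 <- matrix(NA_integer_, n, ns,
                         dimnames = list(samples$sample_id, snvs$id))
  with_seed(child_seed(seed, "haplotypes"), {
    for (b in model$blocks$block) {
      idx <- which(snvs$block == b)
      if (!length(idx)) next
      f <- model$blocks$hap_freq[model$blocks$block == b]
      for (h in 1:2) {
        onA <- stats::runif(n) < f
        m <- outer(onA, snvs$on_hapA[idx], FUN = function(a, s) as.integer(a == s))
        if (h == 1) hap1[, idx] <- m else hap2[, idx] <- m
      }
    }
    for (sv in model$svs) {
      al <- sv$alleles$name
      sv_hap[[sv$id]] <- cbind(sample(al, n, TRUE, prob = sv$alleles$freq),
                               sample(al, n, TRUE, prob = sv$alleles$freq))
      rownames(sv_hap[[sv$id]]) <- samples$sample_id
    }
  })

  # remove SNV alleles on haplotypes whose SV allele deletes their position
  for (sv in model$svs) {
    dr <- sv$deleted_ranges
    if (is.null(dr) || !length(dr)) next
    for (al in names(dr)) {
      for (rng in dr[[al]]) {
        hit <- which(!is.na(snvs$containing_sv) & snvs$containing_sv == sv$id &
                       snvs$position >= rng[1] & snvs$position <= rng[2])
        if (!length(hit)) next
        hap1[sv_hap[[sv$id]][, 1] == al, hit] <- NA_integer_
        hap2[sv_hap[[sv$id]][, 2] == al, hit] <- NA_integer_
      }
    }
  }

  noise <- matrix(1, n, length(genes), dimnames = list(samples$sample_id, genes))
  if (model$noise_sd > 0) {
    with_seed(child_seed(seed, "noise"), {
      noise[] <- exp(stats::rnorm(n * length(genes), 0, model$noise_sd))
    })
  }

  structure(list(model = model, seed = as.integer(seed), samples = samples,
                 sv_hap = sv_hap, snv_hap1 = hap1, snv_hap2 = hap2,
                 noise = noise, clones = NULL, truth = NULL),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples, %d genes, %d SNVs, %d SVs, seed %d%s\n",
              nrow(x$samples), nrow(x$model$genes), ncol(x$snv_hap1),
              length(x$sv_hap), x$seed,
              if (is.null(x$clones)) "" else sprintf(", %d clones", nrow(x$clones))))
  invisible(x)
}

# per-haplotype gene copy matrices (samples x genes), h in 1:2
hap_copy_matrix <- function(cohort, h) {
  genes <- cohort$model$genes$name
  cm <- matrix(1, nrow(cohort$samples), length(genes),
               dimnames = list(cohort$samples$sample_id, genes))
  for (sv in cohort$model$svs) {
    carried <- cohort$sv_hap[[sv$id]][, h]
    for (al in sv$alleles$name) {
      rows <- carried == al
      if (!any(rows)) next
      cm[rows, names(sv$copy_map[[al]])] <-
        matrix(sv$copy_map[[al]], sum(rows), length(sv$copy_map[[al]]), byrow = TRUE)
    }
  }
  cm
}

#' Diploid gene copy number
#'
#' Sums the two haplotypes' SV-allele gene-to-copy maps; genes outside any SV
#' contribute one copy per haplotype.
#'
#' @param cohort a `sim_cohort`.
#' @param sample_id a single sample id, or NULL for the full samples x genes
#'   matrix.
#' @return Named integer vector (one sample) or matrix (all samples).
#' @export
gene_copy_number <- function(cohort, sample_id = NULL) {
  cn <- hap_copy_matrix(cohort, 1) + hap_copy_matrix(cohort, 2)
  mode(cn) <- "integer"
  if (is.null(sample_id)) return(cn)
  if (!sample_id %in% rownames(cn)) stopf("unknown sample '%s'", sample_id)
  cn[sample_id, ]
}

# per-haplotype recombination weights (copies x baseline x cis multipliers),
# before covariate/noise multipliers which are haplotype-symmetric
hap_weights <- function(cohort, h) {
  model <- cohort$model
  w <- hap_copy_matrix(cohort, h)
  w <- sweep(w, 2, model$baseline_weights[colnames(w)], `*`)
  hap <- if (h == 1) cohort$snv_hap1 else cohort$snv_hap2
  if (nrow(model$effects)) {
    for (i in seq_len(nrow(model$effects))) {
      e <- model$effects[i, ]
      carrier <- !is.na(hap[, e$variant]) & hap[, e$variant] == 1L
      w[carrier, e$gene] <- w[carrier, e$gene] * e$multiplier
    }
  }
  w
}

#' True per-gene usage probabilities
#'
#' Computes each sample's ground-truth V(D)J gene-usage probability vectors:
#' the unnormalised weight of a gene is the sum over the two haplotypes of
#' copies x baseline weight x active cis multipliers, times the sample's
#' platform batch factor, age factor and lognormal noise factor; weights are
#' normalised to probabilities within each segment class (every clone uses
#' exactly one V, one D and one J gene, so usage is class-conditional by
#' construction). A gene with diploid copy number 0 has probability exactly 0.
#'
#' @param cohort a `sim_cohort`.
#' @param sample_id a single sample id, or NULL for all samples.
#' @return For one sample, a list of named probability vectors (`V`, `D`,
#'   `J` as present in the model); for all samples, a list of samples x genes
#'   probability matrices per segment class.
#' @export
simulate_usage_probs <- function(cohort, sample_id = NULL) {
  model <- cohort$model
  w <- hap_weights(cohort, 1) + hap_weights(cohort, 2)
  cov <- model$covariate_model
  pf <- cov$platform_effects[colnames(w), cohort$samples$platform, drop = FALSE]
  w <- w * t(pf)
  slope <- cov$age_slope[colnames(w)]
  if (any(slope != 0)) w <- w * exp(outer(cohort$samples$age, slope))
  w <- w * cohort$noise[, colnames(w), drop = FALSE]

  segs <- split(model$genes$name, model$genes$segment)
  segs <- segs[order(match(names(segs), c("V", "D", "J")))]
  out <- lapply(segs, function(gs) {
    ws <- w[, gs, drop = FALSE]
    tot <- rowSums(ws)
    if (any(tot == 0))
      stopf("degenerate sample (all %s genes deleted): %s",
            model$genes$segment[match(gs[1], model$genes$name)],
            paste(rownames(ws)[tot == 0], collapse = ", "))
    ws / tot
  })
  if (is.null(sample_id)) return(out)
  if (!sample_id %in% cohort$samples$sample_id) stopf("unknown sample '%s'", sample_id)
  lapply(out, function(m) m[sample_id, ])
}

#' Simulate clone-level repertoires
#'
#' Draws each sample's B cell clones multinomially from its true usage
#' probability vectors: the V, D and J gene of a clone are drawn
#' independently from their class-specific vectors. For genes with a
#' coding-allele definition, each clone's allele label is inherited from the
#' originating haplotype (chosen proportionally to the haplotype's weight
#' contribution for that gene); all other calls carry the `*01` label.
#'
#' @param cohort a `sim_cohort`.
#' @param sample_id single sample id or NULL for all samples.
#' @param n_clones clone count per sample; NULL draws negative-binomial
#'   counts around the model's `mean_clones`.
#' @param seed seed for the clone-sampling stage.
#' @param isotype isotype label ("IgM" or "IgG") written to `c_call` as
#'   IGHM/IGHG.
#' @return A `data.table` in AIRR Rearrangement column order: sequence_id,
#'   sample_id, c_call, v_call, d_call, j_call, junction_length,
#'   duplicate_count, clone_id.
#' @export
simulate_clones <- function(cohort, sample_id = NULL, n_clones = NULL, seed,
                            isotype = "IgM") {
  model <- cohort$model
  stopifnot(isotype %in% c("IgM", "IgG"))
  ids <- sample_id %||% cohort$samples$sample_id
  if (!all(ids %in% cohort$samples$sample_id)) stopf("unknown sample id")
  if (!is.null(n_clones) && any(n_clones < 1)) stopf("n_clones must be >= 1")
  probs <- simulate_usage_probs(cohort)
  cm <- model$clone_model
  c_call <- if (isotype == "IgM") "IGHM" else "IGHG"
  coding <- model$coding_alleles
  hw1 <- hap_weights(cohort, 1); hw2 <- hap_weights(cohort, 2)
  # haplotype coding-allele labels per tagged gene
  lab <- function(h, gene_i) {
    hap <- if (h == 1) cohort$snv_hap1 else cohort$snv_hap2
    alt <- hap[, coding$tag_snv[gene_i]]
    ifelse(is.na(alt), NA_character_,
           ifelse(alt == 1L, coding$alt_label[gene_i], coding$ref_label[gene_i]))
  }

  out <- vector("list", length(ids))
  with_seed(child_seed(seed, "clones"), {
    nc <- if (is.null(n_clones)) {
      pmax(cm$min_clones,
           stats::rnbinom(length(ids), mu = cm$mean_clones, size = cm$dispersion))
    } else rep_len(n_clones, length(ids))
    for (k in seq_along(ids)) {
      s <- ids[k]
      si <- match(s, cohort$samples$sample_id)
      n <- nc[k]
      calls <- lapply(probs, function(pm) {
        p <- pm[s, ]
        cnt <- as.vector(stats::rmultinom(1, n, p))
        sample(rep.int(names(p), cnt))  # shuffle clone order
      })
      vg <- calls[["V"]] %||% character(0)
      dg <- calls[["D"]]; jg <- calls[["J"]]
      allele <- function(gene_calls) {
        al <- rep("*01", length(gene_calls))
        for (gi in seq_len(nrow(coding))) {
          g <- coding$gene[gi]
          idx <- which(gene_calls == g)
          if (!length(idx)) next
          w1 <- hw1[si, g]; w2 <- hw2[si, g]
          if (w1 + w2 == 0) next
          use1 <- stats::runif(length(idx)) < w1 / (w1 + w2)
          l1 <- lab(1, gi)[si]; l2 <- lab(2, gi)[si]
          al[idx] <- ifelse(use1, l1, l2)
          al[idx][is.na(al[idx])] <- "*01"
        }
        al
      }
      dt <- data.table::data.table(
        sequence_id = sprintf("%s_seq%06d", s, seq_len(n)),
        sample_id = s, c_call = c_call,
        v_call = paste0(vg, allele(vg)),
        d_call = if (is.null(dg)) NA_character_ else paste0(dg, "*01"),
        j_call = if (is.null(jg)) NA_character_ else paste0(jg, "*01"),
        junction_length = sample(cm$junction_range[1]:cm$junction_range[2], n, TRUE),
        duplicate_count = 1L + stats::rgeom(n, cm$dup_geom_prob),
        clone_id = sprintf("%s_cl%06d", s, seq_len(n)))
      out[[k]] <- dt
    }
  })
  data.table::rbindlist(out)
}

#' Simulate a complete cohort with ground truth
#'
#' Convenience orchestrator: [simulate_haplotypes()], then
#' [simulate_clones()], then records the ground-truth registry (cis effect
#' map, SV-to-gene maps, expected lead variant per affected gene, and the
#' true usage probability matrices).
#'
#' @inheritParams simulate_haplotypes
#' @param n_clones per-sample clone count (NULL = negative-binomial draw).
#' @param isotype isotype label for the clone table.
#' @return A `sim_cohort` with `$clones` and `$truth` populated.
#' @export
simulate_cohort <- function(model, n_samples = 150, seed = 1,
                            n_clones = NULL, isotype = "IgM") {
  cohort <- simulate_haplotypes(model, n_samples, seed)
  cohort$clones <- simulate_clones(cohort, n_clones = n_clones, seed = seed,
                                   isotype = isotype)
  cohort$truth <- cohort_truth(cohort)
  cohort
}

# Ground-truth registry: which variant should lead which (merged) usage gene.
cohort_truth <- function(cohort) {
  model <- cohort$model
  mm <- default_merge_map()
  merged <- function(g) ifelse(g %in% names(mm), unname(mm[g]), g)
  leads <- list()
  for (sv in model$svs) {
    ref <- sv$alleles$name[1]
    spanned <- names(sv$copy_map[[ref]])
    affected <- vapply(spanned, function(g) {
      any(vapply(sv$alleles$name[-1], function(a) sv$copy_map[[a]][[g]] != 1, TRUE))
    }, TRUE)
    gset <- setdiff(unique(merged(spanned[affected])), default_exclusions())
    if (length(gset))
      leads[[sv$id]] <- data.frame(gene = gset, causal_variant = sv$id,
                                   causal_type = "SV", stringsAsFactors = FALSE)
  }
  if (nrow(model$effects)) {
    for (i in seq_len(nrow(model$effects))) {
      e <- model$effects[i, ]
      g <- merged(e$gene)
      # a cis SNV on a gene whose copy number an SV also alters is a
      # secondary (conditional) signal, not the expected lead
      in_sv <- any(vapply(leads, function(df) g %in% df$gene, TRUE))
      leads[[paste0("eff_", i)]] <- data.frame(
        gene = g, causal_variant = e$variant,
        causal_type = if (in_sv) "SNV_secondary" else "SNV",
        stringsAsFactors = FALSE)
    }
  }
  list(effects = model$effects,
       expected_leads = do.call(rbind, unname(leads)),
       usage_probs = simulate_usage_probs(cohort),
       copy_number = gene_copy_number(cohort))
}

#' Synthetic regulatory feature track
#'
#' Generates a small BED-style table of synthetic regulatory intervals
#' (labelled with cCRE-like classes) on the model contig: for each class a
#' few intervals are centred on randomly chosen SNVs and a few placed in
#' variant-free background, so overlap and enrichment code paths are
#' exercised. This is a synthetic stand-in, not ENCODE data.
#'
#' @param model a `locus_model`.
#' @param seed RNG seed.
#' @param classes feature class labels.
#' @param n_on,n_off intervals per class on SNVs / in background.
#' @param width interval width in bp.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `class`.
#' @export
simulate_features <- function(model, seed = 1,
                              classes = c("CTCF-only,CTCF-bound",
                                          "dELS,CTCF-bound",
                                          "DNase-H3K4me3", "PLS"),
                              n_on = 6, n_off = 6, width = 300L) {
  with_seed(child_seed(seed, "features"), {
    out <- lapply(classes, function(cl) {
      on_pos <- sample(model$snvs$position, n_on)
      off_pos <- sample(setdiff(seq(1000L, model$locus_length - 1000L, by = 997L),
                                model$snvs$position), n_off)
      start0 <- c(on_pos - sample(width, n_on, TRUE), off_pos)
      data.frame(chrom = model$contig, start = pmax(0L, as.integer(start0)),
                 end = pmax(0L, as.integer(start0)) + width, class = cl,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Synthetic GWAS-catalog-style table
#'
#' Emits rows mimicking an NHGRI-EBI catalog export restricted to the locus:
#' some rows sit on model SNV positions (half below the significance cut,
#' half above) and some on background positions. Synthetic stand-in for the
#' real catalog.
#'
#' @param model a `locus_model`.
#' @param seed RNG seed.
#' @param n_on number of rows placed on model SNVs.
#' @return data.frame with columns SNPS, CHR_ID, CHR_POS, `DISEASE/TRAIT`,
#'   `P-VALUE`, `STUDY ACCESSION`.
#' @export
simulate_gwas_table <- function(model, seed = 1, n_on = 12) {
  traits <- c("Rheumatic heart disease", "Kawasaki disease", "Estradiol levels",
              "IgG glycosylation", "Microglial activation")
  with_seed(child_seed(seed, "gwas"), {
    idx <- sample(nrow(model$snvs), n_on)
    p <- ifelse(seq_len(n_on) %% 2 == 0,
                10^stats::runif(n_on, -12, -6.5),  # below the 4e-6 cut
                10^stats::runif(n_on, -5.3, -3))   # above it
    data.frame(
      SNPS = model$snvs$id[idx], CHR_ID = model$contig,
      CHR_POS = model$snvs$position[idx],
      `DISEASE/TRAIT` = sample(traits, n_on, TRUE),
      `P-VALUE` = signif(p, 3),
      `STUDY ACCESSION` = sprintf("GCST9%05d", sample(1e5, n_on)),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
}
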