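#' Construct a locus model for the synthetic IGH cohort generator
#'
#' A locus model is the full generative specification of a synthetic IGH-like
#' locus: the ordered V/D/J gene segments, structural variants (SVs) whose
#' alleles change per-haplotype gene copy number (including deletion alleles
#' that remove SNV positions and thereby create hemizygous or missing SNV
#' genotypes), SNVs organised into LD blocks drawn from two-haplotype pools,
#' per-haplotype cis-regulatory multiplicative effects on recombination
#' propensity, per-gene baseline usage weights, coding-allele labels tagged to
#' block haplotypes, and covariate (age, sequencing platform) effects.
#'
#' @param genes data.frame with columns `name`, `segment` ("V","D","J"),
#'   `position` (1-based locus coordinate) and `functional` (logical).
#' @param svs named list of SV descriptors; each a list with `id`, `span`
#'   (length-2 integer), `alleles` (data.frame `name`, `freq`, frequencies
#'   summing to 1), `copy_map` (named list: allele -> named numeric vector of
#'   per-haplotype copies for every spanned gene; the first allele is the
#'   reference and must map every spanned gene to 1), and optional
#'   `deleted_ranges` (named list: allele -> list of `c(start, end)` intervals
#'   whose SNV positions are absent from haplotypes carrying that allele).
#' @param blocks data.frame with columns `block` and `hap_freq` (frequency of
#'   pool haplotype "A" within the block; the pool has two haplotypes so all
#'   segregating SNVs within a block are in perfect LD).
#' @param snvs data.frame with columns `id`, `position`, `block`, `on_hapA`
#'   (logical; TRUE if the alternate allele rides pool haplotype A) and
#'   `containing_sv` (SV id or NA). Every SNV positioned inside an SV span
#'   must reference that SV.
#' @param effects data.frame with columns `variant` (SNV id), `gene` and
#'   `multiplier` (>0); the multiplier scales the gene's recombination weight
#'   on each haplotype carrying the alternate allele.
#' @param baseline_weights named numeric vector of strictly positive per-gene
#'   usage weights.
#' @param coding_alleles data.frame with columns `gene`, `tag_snv`,
#'   `ref_label`, `alt_label`; haplotypes carry the ref/alt coding allele of
#'   the gene according to their allele at the tag SNV.
#' @param covariate_model list with `age_range`, `age_slope` (per-gene addend
#'   to the log-weight per year, usually 0), `platforms`, `platform_probs` and
#'   `platform_effects` (genes x platforms multiplicative matrix, first
#'   column 1).
#' @param noise_sd standard deviation of the per-sample, per-gene lognormal
#'   weight noise (inter-individual usage variation not explained by
#'   genotype).
#' @param clone_model list with `mean_clones`, `dispersion` (negative-binomial
#'   size), `min_clones`, `dup_geom_prob` and `junction_range`.
#' @param contig contig name used in emitted VCFs.
#' @param locus_length locus length in bp.
#'
#' @return An object of class `locus_model`.
#' @seealso [default_locus_model()], [simulate_cohort()]
#' @export
locus_model <- function(genes, svs = list(), blocks = NULL, snvs = NULL,
                        effects = NULL, baseline_weights, coding_alleles = NULL,
                        covariate_model = NULL, noise_sd = 0.3,
                        clone_model = NULL, contig = "igh_sim",
                        locus_length = 1200000L) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(blocks)) blocks <- data.frame(block = integer(), hap_freq = numeric())
  if (is.null(snvs)) {
    snvs <- data.frame(id = character(), position = integer(), block = integer(),
                       on_hapA = logical(), containing_sv = character())
  }
  if (is.null(effects)) {
    effects <- data.frame(variant = character(), gene = character(),
                          multiplier = numeric())
  }
  if (is.null(coding_alleles)) {
    coding_alleles <- data.frame(gene = character(), tag_snv = character(),
                                 ref_label = character(), alt_label = character())
  }
  if (is.null(covariate_model)) {
    covariate_model <- list(
      age_range = c(18, 75),
      age_slope = stats::setNames(rep(0, nrow(genes)), genes$name),
      platforms = c("P1", "P2", "P3"),
      platform_probs = c(0.5, 0.3, 0.2),
      platform_effects = matrix(1, nrow(genes), 3,
                                dimnames = list(genes$name, c("P1", "P2", "P3"))))
  }
  if (is.null(clone_model)) {
    clone_model <- list(mean_clones = 9038, dispersion = 8, min_clones = 500,
                        dup_geom_prob = 0.35, junction_range = c(30L, 70L))
  }
  model <- structure(list(
    contig = contig, locus_length = as.integer(locus_length),
    genes = genes, svs = svs, blocks = blocks, snvs = snvs, effects = effects,
    baseline_weights = baseline_weights, coding_alleles = coding_alleles,
    covariate_model = covariate_model, noise_sd = noise_sd,
    clone_model = clone_model), class = "locus_model")
  validate_locus_model(model)
  model
}

#' Validate a locus model against its structural invariants
#'
#' Checks allele-frequency simplexes, nonnegative-integer copy maps, the
#' reference-allele convention (1 copy per spanned gene per haplotype),
#' strictly positive baseline weights and effect multipliers, and that every
#' SNV placed inside an SV span references that SV (so hemizygosity can be
#' derived during simulation).
#'
#' @param model a `locus_model`.
#' @return The model, invisibly; errors on the first violated invariant.
#' @export
validate_locus_model <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  g <- model$genes
  if (!all(c("name", "segment", "position", "functional") %in% names(g)))
    stopf("genes table is missing required columns")
  if (anyDuplicated(g$name)) stopf("duplicate gene names in model")
  if (!all(g$segment %in% c("V", "D", "J"))) stopf("gene segment must be V, D or J")
  bw <- model$baseline_weights
  if (!all(g$name %in% names(bw))) stopf("baseline_weights must cover every gene")
  if (any(!is.finite(bw)) || any(bw <= 0)) stopf("baseline_weights must be strictly positive")
  for (sv in model$svs) {
    f <- sv$alleles$freq
    if (any(f < 0 | f > 1)) stopf("SV %s: allele frequencies must lie in [0,1]", sv$id)
    if (abs(sum(f) - 1) > 1e-9) stopf("SV %s: allele frequencies must sum to 1", sv$id)
    if (all(f == 0)) stopf("SV %s: zero-frequency-only allele list", sv$id)
    ref <- sv$alleles$name[1]
    spanned <- names(sv$copy_map[[ref]])
    if (!all(unlist(sv$copy_map) >= 0) ||
        any(unlist(sv$copy_map) != round(unlist(sv$copy_map))))
      stopf("SV %s: copy-map values must be nonnegative integers", sv$id)
    if (!all(sv$copy_map[[ref]] == 1))
      stopf("SV %s: reference allele must map every spanned gene to 1 copy", sv$id)
    for (al in sv$alleles$name) {
      if (!setequal(names(sv$copy_map[[al]]), spanned))
        stopf("SV %s: allele %s copy map must cover the spanned gene set", sv$id, al)
    }
    if (!all(spanned %in% g$name)) stopf("SV %s: spans unknown genes", sv$id)
  }
  if (any(model$effects$multiplier <= 0))
    stopf("effect multipliers must be strictly positive")
  if (nrow(model$effects) && !all(model$effects$gene %in% g$name))
    stopf("effects reference unknown genes")
  if (nrow(model$effects) && !all(model$effects$variant %in% model$snvs$id))
    stopf("effects reference unknown SNVs")
  s <- model$snvs
  if (nrow(s)) {
    if (anyDuplicated(s$id)) stopf("duplicate SNV ids")
    if (!all(s$block %in% model$blocks$block)) stopf("SNV references unknown LD block")
    for (sv in model$svs) {
      inside <- s$position >= sv$span[1] & s$position <= sv$span[2]
      bad <- inside & (is.na(s$containing_sv) | s$containing_sv != sv$id)
      if (any(bad))
        stopf("SNVs inside SV %s span must reference it (e.g. %s)",
              sv$id, s$id[which(bad)[1]])
    }
  }
  hf <- model$blocks$hap_freq
  if (any(hf < 0 | hf > 1)) stopf("block haplotype frequencies must lie in [0,1]")
  invisible(model)
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %d genes (%s), %d SVs, %d SNVs in %d LD blocks, %d cis effects\n",
              nrow(x$genes),
              paste(sprintf("%d %s", table(factor(x$genes$segment, c("V", "D", "J"))),
                            c("V", "D", "J")), collapse = ", "),
              length(x$svs), nrow(x$snvs), nrow(x$blocks), nrow(x$effects)))
  invisible(x)
}

# Interval helper: gene positions falling inside a span
genes_in_span <- function(genes, span) {
  genes$name[genes$position >= span[1] & genes$position <= span[2]]
}

#' Default synthetic IGH locus model
#'
#' Deterministically constructs the model used throughout the package's tests
#' and examples: 62 genes (44 IGHV, 12 IGHD, 6 IGHJ, including the merge-group
#' members IGHV3-23/-23D, IGHV3-30/-30-3/-30-5/-33, IGHV1-69/-69D,
#' IGHD4-4/IGHD4-11 and the excluded IGHD5-5 and IGHV3-16), three SVs (a
#' 6-gene IGHD-region deletion at allele frequency 0.30, an IGHV3-23D
#' presence/absence event giving diploid copy numbers 2-4 for the merged
#' IGHV3-23 entity, and a 3-allele multi-allelic SV spanning four IGHV genes),
#' about 500 SNVs in 40 two-haplotype LD blocks, two cis-regulatory SNV
#' effects (a primary effect on IGHV3-66 and a secondary effect on IGHD3-3,
#' the latter inside the deletion so it is discoverable only by conditional
#' analysis), coding-allele tags for three IGHV genes, lognormal per-sample
#' usage noise (sd 0.3) and a mild multiplicative platform batch effect.
#'
#' The IGHV3-23/-23D baseline weight is calibrated so that individuals with 2
#' diploid copies of the merged gene have expected usage 7.4%, which under
#' the additive copy-number model implies about 13.8% at 4 copies.
#'
#' @param n_blocks number of LD blocks (default 40).
#' @param snvs_per_block approximate SNVs per block (default 13).
#' @param noise_sd per-sample lognormal usage-noise sd.
#' @return A `locus_model`.
#' @export
default_locus_model <- function(n_blocks = 40L, snvs_per_block = 13L,
                                noise_sd = 0.3) {
  v_names <- c("IGHV6-1", "IGHV1-2", "IGHV1-3", "IGHV4-4", "IGHV2-5", "IGHV3-7",
               "IGHV3-64D", "IGHV5-10-1", "IGHV1-8", "IGHV3-9", "IGHV3-11",
               "IGHV3-13", "IGHV3-15", "IGHV3-16", "IGHV1-18", "IGHV3-20",
               "IGHV3-21", "IGHV3-23", "IGHV3-23D", "IGHV1-24", "IGHV2-26",
               "IGHV4-28", "IGHV3-30", "IGHV3-30-3", "IGHV4-31", "IGHV3-30-5",
               "IGHV3-33", "IGHV4-34", "IGHV4-39", "IGHV3-43", "IGHV1-46",
               "IGHV3-48", "IGHV3-49", "IGHV5-51", "IGHV3-53", "IGHV4-59",
               "IGHV4-61", "IGHV3-64", "IGHV3-66", "IGHV1-69", "IGHV1-69D",
               "IGHV2-70D", "IGHV3-72", "IGHV3-74")
  d_names <- c("IGHD1-1", "IGHD2-2", "IGHD3-3", "IGHD4-4", "IGHD4-11",
               "IGHD5-5", "IGHD6-6", "IGHD1-7", "IGHD2-8", "IGHD3-9",
               "IGHD5-18", "IGHD6-13")
  j_names <- paste0("IGHJ", 1:6)
  genes <- data.frame(
    name = c(j_names, d_names, v_names),
    segment = c(rep("J", 6), rep("D", 12), rep("V", 44)),
    position = c(2000L + (1:6) * 600L,
                 20000L + (0:11) * 4000L,
                 100000L + (0:43) * 22000L),
    functional = TRUE, stringsAsFactors = FALSE)
  genes$functional[genes$name == "IGHV3-16"] <- FALSE

  pos_of <- function(nm) genes$position[match(nm, genes$name)]

  # IGHD-region deletion: removes IGHD3-3 .. IGHD2-8 (six usage-relevant
  # genes plus the excluded IGHD5-5) on the DEL haplotype.
  del_genes <- c("IGHD3-3", "IGHD4-4", "IGHD4-11", "IGHD5-5", "IGHD6-6",
                 "IGHD1-7", "IGHD2-8")
  del_span <- c(pos_of("IGHD3-3") - 1000L, pos_of("IGHD2-8") + 1000L)
  sv_del <- list(
    id = "DSV_DEL", span = del_span,
    alleles = data.frame(name = c("REF", "DEL"), freq = c(0.70, 0.30)),
    copy_map = list(REF = stats::setNames(rep(1, length(del_genes)), del_genes),
                    DEL = stats::setNames(rep(0, length(del_genes)), del_genes)),
    deleted_ranges = list(DEL = list(del_span)))

  # IGHV3-23D presence/absence: diploid copy number 2-4 for the merged gene.
  dup_genes <- c("IGHV3-23", "IGHV3-23D")
  dup_span <- c(pos_of("IGHV3-23") - 1000L, pos_of("IGHV3-23D") + 1000L)
  sv_dup <- list(
    id = "VSV_DUP", span = dup_span,
    alleles = data.frame(name = c("REF", "DEL23D"), freq = c(0.45, 0.55)),
    copy_map = list(REF = c("IGHV3-23" = 1, "IGHV3-23D" = 1),
                    DEL23D = c("IGHV3-23" = 1, "IGHV3-23D" = 0)),
    deleted_ranges = list(DEL23D = list(c(pos_of("IGHV3-23D") - 1000L, dup_span[2]))))

  # 3-allele multi-allelic SV over four IGHV genes (full and partial deletion).
  msv_genes <- c("IGHV3-64D", "IGHV5-10-1", "IGHV1-8", "IGHV3-9")
  msv_span <- c(pos_of("IGHV3-64D") - 1000L, pos_of("IGHV3-9") + 1000L)
  part_range <- c(pos_of("IGHV1-8") - 1000L, msv_span[2])
  sv_msv <- list(
    id = "VSV_CMPLX", span = msv_span,
    alleles = data.frame(name = c("REF", "DEL", "DELPART"),
                         freq = c(0.50, 0.30, 0.20)),
    copy_map = list(
      REF = stats::setNames(rep(1, 4), msv_genes),
      DEL = stats::setNames(rep(0, 4), msv_genes),
      DELPART = c("IGHV3-64D" = 1, "IGHV5-10-1" = 1, "IGHV1-8" = 0, "IGHV3-9" = 0)),
    deleted_ranges = list(DEL = list(msv_span), DELPART = list(part_range)))
  svs <- list(DSV_DEL = sv_del, VSV_DUP = sv_dup, VSV_CMPLX = sv_msv)

  with_seed(860301, {
    blocks <- data.frame(block = seq_len(n_blocks),
                         hap_freq = round(stats::runif(n_blocks, 0.15, 0.85), 3))
    # fixed frequencies for the two effect-carrying blocks
    blocks$hap_freq[30] <- 0.40
    blocks$hap_freq[10] <- 0.45
    # block genomic windows: blocks 1-2 inside the D deletion, 3-4 inside the
    # mSV (block 4 within the partial-deletion sub-interval), rest spread out.
    n_snv <- snvs_per_block + (blocks$block %% 3L) - 1L
    snv_list <- vector("list", n_blocks)
    win_starts <- round(seq(250000, 1150000, length.out = n_blocks - 4))
    wi <- 1L
    for (b in seq_len(n_blocks)) {
      k <- n_snv[b]
      if (b == 1L) pos <- seq(del_span[1] + 200L, del_span[1] + 8000L, length.out = k)
      else if (b == 2L) pos <- seq(del_span[2] - 8000L, del_span[2] - 200L, length.out = k)
      else if (b == 3L) pos <- seq(msv_span[1] + 200L, part_range[1] - 2000L, length.out = k)
      else if (b == 4L) pos <- seq(part_range[1] + 200L, part_range[2] - 200L, length.out = k)
      else { pos <- win_starts[wi] + seq(0, 6000, length.out = k); wi <- wi + 1L }
      pos <- as.integer(round(pos))
      # keep free blocks clear of SV spans
      if (b > 4L) {
        for (sv in svs) {
          hit <- pos >= sv$span[1] & pos <= sv$span[2]
          pos[hit] <- pos[hit] + (sv$span[2] - sv$span[1]) + 5000L
        }
      }
      csv <- if (b %in% 1:2) "DSV_DEL" else if (b %in% 3:4) "VSV_CMPLX" else NA_character_
      snv_list[[b]] <- data.frame(
        id = sprintf("snv_%02d_%02d", b, seq_len(k)),
        position = pos, block = b,
        on_hapA = stats::runif(k) < 0.5,
        containing_sv = csv, stringsAsFactors = FALSE)
    }
    snvs <- do.call(rbind, snv_list)

    # cis effects: primary on IGHV3-66 (free block), secondary on IGHD3-3
    # (gene inside the deletion; SNV outside it, so the effect segregates
    # within the deletion's homozygous-reference stratum).
    eff1 <- "snv_30_05"; eff2 <- "snv_10_03"
    snvs$on_hapA[snvs$id %in% c(eff1, eff2)] <- TRUE
    effects <- data.frame(variant = c(eff1, eff2),
                          gene = c("IGHV3-66", "IGHD3-3"),
                          multiplier = c(1.8, 1.7))

    coding_alleles <- data.frame(
      gene = c("IGHV3-66", "IGHV3-53", "IGHV3-64"),
      tag_snv = c(eff1, "snv_31_03", "snv_29_02"),
      ref_label = c("*03", "*01", "*01"),
      alt_label = c("*01", "*02", "*02"), stringsAsFactors = FALSE)

    bw <- stats::setNames(exp(stats::rnorm(nrow(genes), 0, 0.6)), genes$name)
    # J genes: smoother profile
    bw[j_names] <- c(0.4, 0.9, 1.1, 2.2, 1.0, 2.6)

    # calibrate the merged IGHV3-23 entity: expected usage 7.4% at diploid
    # copy number 2 given the expected total V-segment weight of the rest.
    vg <- genes$name[genes$segment == "V"]
    other_v <- setdiff(vg, dup_genes)
    exp_hap_copies <- stats::setNames(rep(1, length(other_v)), other_v)
    for (gname in msv_genes) {
      cm <- sv_msv$copy_map
      exp_hap_copies[gname] <- sum(sv_msv$alleles$freq *
                                     vapply(sv_msv$alleles$name,
                                            function(a) cm[[a]][[gname]], 0))
    }
    eff_mult <- stats::setNames(rep(1, length(other_v)), other_v)
    eff_mult["IGHV3-66"] <- 1 + 0.40 * (1.8 - 1)
    R <- sum(2 * exp_hap_copies * bw[other_v] * eff_mult)
    w23 <- (0.074 / (1 - 0.074)) * R / 2
    bw["IGHV3-23"] <- w23
    bw["IGHV3-23D"] <- w23
    # genes excluded from usage analysis keep small weights
    bw["IGHD5-5"] <- 0.05
    bw["IGHV3-16"] <- 0.02

    platforms <- c("P1", "P2", "P3")
    pf <- matrix(1, nrow(genes), 3, dimnames = list(genes$name, platforms))
    pf[, 2] <- exp(stats::rnorm(nrow(genes), 0, 0.08))
    pf[, 3] <- exp(stats::rnorm(nrow(genes), 0, 0.08))
    covariate_model <- list(
      age_range = c(18, 75),
      age_slope = stats::setNames(rep(0, nrow(genes)), genes$name),
      platforms = platforms, platform_probs = c(0.5, 0.3, 0.2),
      platform_effects = pf)
  })

  locus_model(genes = genes, svs = svs, blocks = blocks, snvs = snvs,
              effects = effects, baseline_weights = bw,
              coding_alleles = coding_alleles,
              covariate_model = covariate_model, noise_sd = noise_sd)
}

#' Null locus model (no genetic effects) for calibration studies
#'
#' Builds a model with `n_genes` V-segment genes, `n_snvs` SNVs in
#' two-haplotype LD blocks, no SVs and an empty effect map, so that gene
#' usage is statistically independent of genotype. Used for type-I-error
#' calibration of the association scan.
#'
#' @param n_genes,n_snvs,n_blocks model dimensions.
#' @param noise_sd per-sample lognormal usage-noise sd.
#' @param mean_clones mean clones per simulated repertoire.
#' @return A `locus_model`.
#' @export
null_locus_model <- function(n_genes = 200L, n_snvs = 500L, n_blocks = 40L,
                             noise_sd = 0.3, mean_clones = 9038) {
  genes <- data.frame(
    name = sprintf("IGHVS-%03d", seq_len(n_genes)), segment = "V",
    position = 10000L + seq_len(n_genes) * 4000L, functional = TRUE,
    stringsAsFactors = FALSE)
  with_seed(911017, {
    blocks <- data.frame(block = seq_len(n_blocks),
                         hap_freq = round(stats::runif(n_blocks, 0.15, 0.85), 3))
    bsz <- rep(floor(n_snvs / n_blocks), n_blocks)
    bsz[seq_len(n_snvs - sum(bsz))] <- bsz[seq_len(n_snvs - sum(bsz))] + 1L
    blk <- rep(blocks$block, bsz)
    snvs <- data.frame(
      id = sprintf("snv_%04d", seq_len(n_snvs)),
      position = as.integer(max(genes$position) + 50000L + seq_len(n_snvs) * 120L),
      block = blk, on_hapA = stats::runif(n_snvs) < 0.5,
      containing_sv = NA_character_, stringsAsFactors = FALSE)
    bw <- stats::setNames(exp(stats::rnorm(n_genes, 0, 0.6)), genes$name)
  })
  cm <- list(mean_clones = mean_clones, dispersion = 8, min_clones = 500,
             dup_geom_prob = 0.35, junction_range = c(30L, 70L))
  locus_model(genes = genes, svs = list(), blocks = blocks, snvs = snvs,
              baseline_weights = bw, noise_sd = noise_sd, clone_model = cm)
}

#' Write a locus model to a YAML configuration file
#'
#' The YAML schema mirrors the `locus_model` fields one-to-one (tables are
#' written as lists of records, matrices as row-named lists) and round-trips
#' through [read_locus_model()].
#'
#' @param model a `locus_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_locus_model <- function(model, path) {
  validate_locus_model(model)
  ser <- list(
    contig = model$contig, locus_length = model$locus_length,
    genes = model$genes, blocks = model$blocks, snvs = model$snvs,
    effects = model$effects, coding_alleles = model$coding_alleles,
    baseline_weights = as.list(model$baseline_weights),
    svs = lapply(model$svs, function(sv) list(
      id = sv$id, span = sv$span, alleles = sv$alleles,
      copy_map = lapply(sv$copy_map, as.list),
      deleted_ranges = lapply(sv$deleted_ranges %||% list(), function(rl) lapply(rl, as.integer)))),
    covariate_model = list(
      age_range = model$covariate_model$age_range,
      age_slope = as.list(model$covariate_model$age_slope),
      platforms = model$covariate_model$platforms,
      platform_probs = model$covariate_model$platform_probs,
      platform_effects = apply(model$covariate_model$platform_effects, 1,
                               as.list, simplify = FALSE)),
    noise_sd = model$noise_sd, clone_model = model$clone_model)
  yaml::write_yaml(ser, path, column.major = FALSE)
  invisible(path)
}

#' Read a locus model from a YAML configuration file
#'
#' @param path file written by [write_locus_model()] (or hand-authored in the
#'   same schema).
#' @return A validated `locus_model`.
#' @export
read_locus_model <- function(path) {
  y <- yaml::read_yaml(path)
  as_df <- function(x, cols) {
    if (length(x) == 0) return(NULL)
    df <- data.table::rbindlist(x)
    as.data.frame(df)[, cols, drop = FALSE]
  }
  genes <- as_df(y$genes, c("name", "segment", "position", "functional"))
  blocks <- as_df(y$blocks, c("block", "hap_freq"))
  snvs <- as_df(y$snvs, c("id", "position", "block", "on_hapA", "containing_sv"))
  if (!is.null(snvs)) snvs$containing_sv <- as.character(snvs$containing_sv)
  effects <- as_df(y$effects, c("variant", "gene", "multiplier"))
  coding <- as_df(y$coding_alleles, c("gene", "tag_snv", "ref_label", "alt_label"))
  svs <- lapply(y$svs, function(sv) list(
    id = sv$id, span = as.integer(unlist(sv$span)),
    alleles = as.data.frame(data.table::rbindlist(sv$alleles)),
    copy_map = lapply(sv$copy_map, function(m) unlist(m)),
    deleted_ranges = lapply(sv$deleted_ranges, function(rl)
      lapply(rl, function(r) as.integer(unlist(r))))))
  pe <- y$covariate_model$platform_effects
  pemat <- do.call(rbind, lapply(pe, unlist))
  colnames(pemat) <- y$covariate_model$platforms
  covariate_model <- list(
    age_range = as.numeric(unlist(y$covariate_model$age_range)),
    age_slope = unlist(y$covariate_model$age_slope),
    platforms = unlist(y$covariate_model$platforms),
    platform_probs = as.numeric(unlist(y$covariate_model$platform_probs)),
    platform_effects = pemat)
  locus_model(genes = genes, svs = svs, blocks = blocks, snvs = snvs,
              effects = effects, baseline_weights = unlist(y$baseline_weights),
              coding_alleles = coding, covariate_model = covariate_model,
              noise_sd = y$noise_sd, clone_model = y$clone_model,
              contig = y$contig, locus_length = y$locus_length)
}
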