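#' Construct a hemizygosity-aware genotype matrix
#'
#' Genotype calls are stored as two parallel integer allele matrices
#' (samples x variants): a diploid call has both allele indices set, a
#' hemizygous call has the single allele in `a1` and NA in `a2`, and a
#' missing call has both NA. Allele index 0 is the reference.
#'
#' @param variants data.frame with columns `id`, `position`, `class` (one of
#'   SNV, INDEL, SV, COMPLEX_SV, MSV, TANDEM_REPEAT), `alleles`
#'   (comma-separated, reference first) and optionally `containing_sv`,
#'   `span_start`, `span_end`.
#' @param a1,a2 integer matrices (samples x variants) of allele indices.
#' @param samples character vector of sample ids (rownames of `a1`).
#' @param sv_meta optional named list of SV metadata (copy maps, spans,
#'   deleted ranges) carried through VCF round trips.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, a1, a2, samples = rownames(a1),
                            sv_meta = list()) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "position", "class", "alleles") %in% names(variants)),
            is.matrix(a1), is.matrix(a2),
            all(dim(a1) == dim(a2)), ncol(a1) == nrow(variants))
  if (anyDuplicated(variants$id)) stopf("duplicate variant ids")
  if (!all(variants$class %in% c("SNV", "INDEL", "SV", "COMPLEX_SV", "MSV",
                                 "TANDEM_REPEAT")))
    stopf("unknown variant class")
  if (is.null(variants$containing_sv)) variants$containing_sv <- NA_character_
  n_alleles <- lengths(strsplit(variants$alleles, ","))
  if (any(n_alleles < 2)) stopf("every variant needs >= 2 alleles")
  if (any(variants$class == "SNV" & n_alleles != 2))
    stopf("SNVs must be biallelic")
  variants$n_alleles <- n_alleles
  dimnames(a1) <- dimnames(a2) <- list(samples, variants$id)
  # normalise: hemizygous single allele lives in a1; diploid calls are
  # unphased, stored in sorted order
  flip <- is.na(a1) & !is.na(a2)
  a1[flip] <- a2[flip]; a2[flip] <- NA_integer_
  dip <- !is.na(a1) & !is.na(a2)
  lo <- pmin(a1[dip], a2[dip]); hi <- pmax(a1[dip], a2[dip])
  a1[dip] <- lo; a2[dip] <- hi
  bad <- !is.na(a1) & (a1 >= n_alleles[col(a1)] | a1 < 0)
  bad2 <- !is.na(a2) & (a2 >= n_alleles[col(a2)] | a2 < 0)
  if (any(bad) || any(bad2)) stopf("allele index out of range for its variant")
  structure(list(samples = samples, variants = variants, a1 = a1, a2 = a2,
                 sv_meta = sv_meta), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%s)\n",
              length(x$samples), nrow(x$variants),
              paste(names(table(x$variants$class)),
                    table(x$variants$class), sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Extract variants and/or samples from a genotype matrix
#' @param x a `genotype_matrix`.
#' @param i sample index or ids. @param j variant index or ids.
#' @param ... unused. @param drop unused (always keeps structure).
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_matrix(x$variants[j, , drop = FALSE],
                  x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  samples = x$samples[i], sv_meta = x$sv_meta)
}

#' Derive the genotype matrix of a simulated cohort
#'
#' Collects the cohort's SNVs (with hemizygous and missing calls induced by
#' deletion haplotypes) and SV genotypes into one `genotype_matrix`.
#'
#' @param cohort a `sim_cohort`.
#' @return A `genotype_matrix` with SNV columns followed by SV columns.
#' @export
as_genotype_matrix <- function(cohort) {
  model <- cohort$model
  svdf <- do.call(rbind, lapply(model$svs, function(sv) {
    data.frame(id = sv$id, position = sv$span[1],
               class = if (nrow(sv$alleles) > 2) "MSV" else "SV",
               alleles = paste(sv$alleles$name, collapse = ","),
               containing_sv = NA_character_,
               span_start = sv$span[1], span_end = sv$span[2],
               stringsAsFactors = FALSE)
  }))
  snvdf <- data.frame(id = model$snvs$id, position = model$snvs$position,
                      class = "SNV", alleles = "ref,alt",
                      containing_sv = model$snvs$containing_sv,
                      span_start = NA_integer_, span_end = NA_integer_,
                      stringsAsFactors = FALSE)
  variants <- rbind(snvdf, svdf)
  n <- nrow(cohort$samples)
  sv_a <- function(h) {
    m <- matrix(NA_integer_, n, length(model$svs))
    for (k in seq_along(model$svs)) {
      sv <- model$svs[[k]]
      m[, k] <- match(cohort$sv_hap[[sv$id]][, h], sv$alleles$name) - 1L
    }
    m
  }
  a1 <- cbind(cohort$snv_hap1, sv_a(1))
  a2 <- cbind(cohort$snv_hap2, sv_a(2))
  meta <- lapply(model$svs, function(sv)
    list(id = sv$id, span = sv$span, alleles = sv$alleles$name,
         copy_map = sv$copy_map, deleted_ranges = sv$deleted_ranges))
  genotype_matrix(variants, a1, a2, samples = cohort$samples$sample_id,
                  sv_meta = meta)
}

#' Allele statistics for one variant
#'
#' Counts allele copies (2 per diploid call, 1 per hemizygous, 0 per
#' missing), and derives allele frequencies, minor allele frequency and the
#' number of genotyped samples. For multi-allelic variants MAF is
#' `1 - max(frequency)`.
#'
#' @param gm a `genotype_matrix`.
#' @param variant variant id.
#' @return List with `counts` (named allele-copy counts), `freq`, `maf`
#'   (NA when no sample is genotyped) and `n_genotyped`.
#' @export
allele_stats <- function(gm, variant) {
  j <- match(variant, gm$variants$id)
  if (is.na(j)) stopf("unknown variant '%s'", variant)
  alleles <- strsplit(gm$variants$alleles[j], ",")[[1]]
  a1 <- gm$a1[, j]; a2 <- gm$a2[, j]
  counts <- tabulate(c(a1, a2) + 1L, nbins = length(alleles))
  names(counts) <- alleles
  n_genotyped <- sum(!is.na(a1))
  tot <- sum(counts)
  freq <- if (tot > 0) counts / tot else counts * NA_real_
  maf <- if (tot == 0) NA_real_ else if (length(alleles) == 2) min(freq) else 1 - max(freq)
  list(counts = counts, freq = freq, maf = maf, n_genotyped = n_genotyped)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic locus: given the observed allele
#' counts, the p-value is the total probability of heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Hemizygous samples must be excluded before counting (HWE is defined on
#' diploid genotype frequencies).
#'
#' @param n_AA,n_Aa,n_aa diploid genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("at least one genotyped sample required")
  n_a <- 2 * n_aa + n_Aa       # minor-allele-arbitrary: use 'a' copies
  if (n_a > n) return(hwe_exact_test(n_aa, n_Aa, n_AA))
  if (n_a == 0) return(1)
  # heterozygote counts share the parity of the allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  probs <- numeric(length(hets))
  # probability ratio recurrence in the heterozygote count
  i0 <- length(hets)                      # start at the maximum het count
  probs[i0] <- 1
  if (i0 > 1) {
    for (i in (i0 - 1):1) {
      h <- hets[i + 1]                    # moving from h to h - 2
      naa <- (n_a - h) / 2; nAA <- n - h - naa
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (naa + 1) * (nAA + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stopf("impossible genotype configuration")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# vectorised per-variant summary used by filters
variant_summary <- function(gm) {
  a1 <- gm$a1; a2 <- gm$a2
  n_gt <- colSums(!is.na(a1))
  dip <- !is.na(a2)
  alt1 <- a1 > 0; alt2 <- a2 > 0
  vs <- data.frame(id = gm$variants$id, n_genotyped = n_gt,
                   maf = NA_real_, hwe_p = NA_real_)
  for (j in seq_len(nrow(gm$variants))) {
    st <- allele_stats(gm, gm$variants$id[j])
    vs$maf[j] <- st$maf
    if (gm$variants$class[j] == "SNV") {
      d <- dip[, j]
      nAA <- sum(d & !alt1[, j] & !alt2[, j], na.rm = TRUE)
      nAa <- sum(d & xor(alt1[, j], alt2[, j]), na.rm = TRUE)
      naa <- sum(d & alt1[, j] & alt2[, j], na.rm = TRUE)
      vs$hwe_p[j] <- if (nAA + nAa + naa >= 1) hwe_exact_test(nAA, nAa, naa) else NA_real_
    }
  }
  vs
}

#' Filter to common, well-genotyped, HWE-consistent variants
#'
#' Retains variants genotyped in at least `min_genotyped` samples with
#' MAF >= `maf_min`; SNVs additionally require an exact-test HWE p-value of
#' at least `hwe_min` (computed on diploid calls only). A per-rule removal
#' log records the first rule that removed each variant.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param min_genotyped minimum genotyped sample count (default 40).
#' @param hwe_min minimum HWE exact p for SNVs (default 1e-6).
#' @return List with `matrix` (filtered `genotype_matrix`), `log`
#'   (data.frame variant/rule for removals) and `stats` (per-variant summary).
#' @export
filter_common <- function(gm, maf_min = 0.05, min_genotyped = 40,
                          hwe_min = 1e-6) {
  vs <- variant_summary(gm)
  rule <- rep(NA_character_, nrow(vs))
  rule[is.na(rule) & vs$n_genotyped < min_genotyped] <- "min_genotyped"
  rule[is.na(rule) & (is.na(vs$maf) | vs$maf < maf_min)] <- "maf"
  rule[is.na(rule) & !is.na(vs$hwe_p) & vs$hwe_p < hwe_min] <- "hwe"
  keep <- is.na(rule)
  list(matrix = gm[, which(keep)],
       log = data.frame(variant = vs$id[!keep], rule = rule[!keep],
                        stringsAsFactors = FALSE),
       stats = vs)
}

#' Fill missing genotypes by a simple documented policy
#'
#' Policy `"drop"` leaves missing calls missing (they are excluded pairwise
#' in associations). Policy `"frequency"` draws each missing call from the
#' variant's observed genotype-state distribution (diploid and hemizygous
#' states as observed categories), with one exception: an SNV missing
#' because the sample is homozygous for a deletion allele of its containing
#' SV is never filled.
#'
#' @param gm a `genotype_matrix`.
#' @param policy "drop" or "frequency".
#' @param seed RNG seed for the frequency policy.
#' @return A `genotype_matrix`.
#' @export
impute_missing <- function(gm, policy = c("drop", "frequency"), seed = 1) {
  policy <- match.arg(policy)
  if (policy == "drop") return(gm)
  a1 <- gm$a1; a2 <- gm$a2
  protected <- matrix(FALSE, nrow(a1), ncol(a1))
  for (j in seq_len(nrow(gm$variants))) {
    csv <- gm$variants$containing_sv[j]
    if (is.na(csv) || !csv %in% names(gm$sv_meta)) next
    meta <- gm$sv_meta[[csv]]
    del_al <- names(meta$deleted_ranges %||% list())
    if (!length(del_al)) next
    k <- match(csv, gm$variants$id)
    if (is.na(k)) next
    del_idx <- match(del_al, meta$alleles) - 1L
    homdel <- !is.na(gm$a1[, k]) & !is.na(gm$a2[, k]) &
      gm$a1[, k] %in% del_idx & gm$a2[, k] %in% del_idx
    protected[homdel, j] <- TRUE
  }
  with_seed(child_seed(seed, "impute"), {
    for (j in seq_len(ncol(a1))) {
      miss <- is.na(a1[, j]) & !protected[, j]
      if (!any(miss)) next
      obs <- which(!is.na(a1[, j]))
      if (!length(obs)) next
      pick <- obs[sample.int(length(obs), sum(miss), replace = TRUE)]
      a1[miss, j] <- a1[pick, j]
      a2[miss, j] <- a2[pick, j]
    }
  })
  genotype_matrix(gm$variants, a1, a2, samples = gm$samples, sv_meta = gm$sv_meta)
}

#' Encode a genotype call as a regression dosage or categorical label
#'
#' Under the default `"haploid-doubled"` policy a hemizygous call counts its
#' single allele as the sample's full dosage (0 or 2 alternate copies),
#' preserving the mean-dosage interpretation of the one remaining
#' chromosome. The `"categorical"` policy returns the genotype label
#' (`"a/b"` diploid, `"a"` hemizygous) for ANOVA-style tests.
#'
#' @param a1,a2 allele indices (NA in `a2` for hemizygous; both NA is a
#'   missing call, which is an error here).
#' @param policy "haploid-doubled" or "categorical".
#' @return Numeric dosage or character label (vectorised).
#' @export
encode_dosage <- function(a1, a2, policy = c("haploid-doubled", "categorical")) {
  policy <- match.arg(policy)
  if (any(is.na(a1))) stopf("cannot encode a MISSING call")
  if (policy == "categorical") {
    return(ifelse(is.na(a2), as.character(a1),
                  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")))
  }
  ifelse(is.na(a2), 2 * (a1 > 0), (a1 > 0) + (a2 > 0))
}

#' Dosage matrix for biallelic-encodable variants
#'
#' @param gm a `genotype_matrix`.
#' @param policy dosage policy (see [encode_dosage()]).
#' @return Numeric samples x variants matrix; NA for missing calls and for
#'   multi-allelic variants (which are never dosage-encoded).
#' @export
dosage_matrix <- function(gm, policy = "haploid-doubled") {
  d <- matrix(NA_real_, length(gm$samples), nrow(gm$variants),
              dimnames = list(gm$samples, gm$variants$id))
  bi <- gm$variants$n_alleles == 2
  hemi <- !is.na(gm$a1) & is.na(gm$a2)
  dip <- !is.na(gm$a2)
  d[dip] <- (gm$a1[dip] > 0) + (gm$a2[dip] > 0)
  d[hemi] <- 2 * (gm$a1[hemi] > 0)
  d[, !bi] <- NA_real_
  d
}

# categorical genotype label matrix (all variant classes)
genotype_labels <- function(gm) {
  lab <- matrix(NA_character_, length(gm$samples), nrow(gm$variants),
                dimnames = list(gm$samples, gm$variants$id))
  ok <- !is.na(gm$a1)
  hemi <- ok & is.na(gm$a2)
  dip <- !is.na(gm$a2)
  lab[dip] <- paste(pmin(gm$a1[dip], gm$a2[dip]),
                    pmax(gm$a1[dip], gm$a2[dip]), sep = "/")
  lab[hemi] <- as.character(gm$a1[hemi])
  lab
}

#' Linkage disequilibrium between two variants
#'
#' Pearson correlation of dosage vectors over pairwise-complete samples.
#'
#' @param gm a `genotype_matrix`.
#' @param v1,v2 variant ids.
#' @param policy dosage policy.
#' @return List with `r`, `r2` and `n` (samples used); `r` is NA (flagged
#'   with a warning) if either vector has zero variance.
#' @export
compute_ld <- function(gm, v1, v2, policy = "haploid-doubled") {
  d <- dosage_matrix(gm[, c(v1, v2)], policy = policy)
  use <- stats::complete.cases(d)
  if (sum(use) < 2) stopf("need >= 2 pairwise-complete samples")
  x <- d[use, 1]; y <- d[use, 2]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero dosage variance; LD undefined")
    return(list(r = NA_real_, r2 = NA_real_, n = sum(use)))
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r * r, n = sum(use))
}

#' Collapse variants in perfect LD into single effective tests
#'
#' Partitions variants into groups by transitive closure of the pairwise
#' relation `r^2 >= r2_threshold`; each group counts as a single test for
#' multiple-testing correction. Multi-allelic variants (no dosage encoding)
#' and zero-variance variants form singleton groups.
#'
#' @param gm a `genotype_matrix`.
#' @param r2_threshold default 1 (perfect LD; compared with a 1e-12
#'   tolerance to absorb floating-point rounding).
#' @param policy dosage policy.
#' @return List with `groups` (list of variant-id vectors, ordered by locus
#'   position), `group_of` (named group index per variant) and
#'   `effective_tests`.
#' @export
collapse_perfect_ld <- function(gm, r2_threshold = 1, policy = "haploid-doubled") {
  ids <- gm$variants$id
  d <- dosage_matrix(gm, policy = policy)
  ok <- which(colSums(!is.na(d)) >= 2 &
                apply(d, 2, function(x) stats::var(x, na.rm = TRUE) > 0))
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (length(ok) > 1) {
    r <- suppressWarnings(stats::cor(d[, ok, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r2 <- r * r
    hit <- which(r2 >= r2_threshold - 1e-12 & upper.tri(r2), arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      i <- ok[hit[k, 1]]; j <- ok[hit[k, 2]]
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_along(ids), find, 1L)
  ord <- order(gm$variants$position, seq_along(ids))
  groups <- split(ids[ord], match(root[ord], unique(root[ord])))
  names(groups) <- NULL
  group_of <- stats::setNames(match(root, unique(root[ord])), ids)
  list(groups = groups, group_of = group_of, effective_tests = length(groups))
}
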