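#' Allele sharing distance between two genotype vectors
#'
#' At each locus where both samples have diploid, non-missing calls, the
#' per-locus distance is 2 minus the size of the multiset intersection of
#' the two allele pairs (0 for identical genotypes, 1 for one shared allele,
#' 2 for none); the ASD is the mean per-locus distance divided by 2, so it
#' lies in \[0, 1\]. Hemizygous and missing loci are skipped.
#'
#' @param g1,g2 genotype vectors as `"a/b"` strings (hemizygous `"a"`,
#'   missing NA), or 2-column integer matrices of allele indices.
#' @return ASD in \[0, 1\]; errors if no shared complete locus exists.
#' @export
allele_sharing_distance <- function(g1, g2) {
  parse <- function(g) {
    if (is.matrix(g)) return(g)
    sp <- strsplit(as.character(g), "/", fixed = TRUE)
    a <- suppressWarnings(vapply(sp, function(x)
      if (length(x) == 2) as.integer(x[1]) else NA_integer_, 1L))
    b <- suppressWarnings(vapply(sp, function(x)
      if (length(x) == 2) as.integer(x[2]) else NA_integer_, 1L))
    cbind(a, b)
  }
  m1 <- parse(g1); m2 <- parse(g2)
  use <- stats::complete.cases(m1) & stats::complete.cases(m2)
  if (!any(use)) stopf("no locus with diploid calls in both samples")
  x1 <- pmin(m1[use, 1], m1[use, 2]); x2 <- pmax(m1[use, 1], m1[use, 2])
  y1 <- pmin(m2[use, 1], m2[use, 2]); y2 <- pmax(m2[use, 1], m2[use, 2])
  shared <- ifelse(x1 == x2,
                   (y1 == x1) + (y2 == x1),
                   ((y1 == x1) | (y2 == x1)) + ((y1 == x2) | (y2 == x2)))
  mean(2 - shared) / 2
}

#' Pairwise allele-sharing-distance matrix
#'
#' @param gm a `genotype_matrix`.
#' @param variant_ids loci to use (e.g. the lead guQTLs); default all.
#' @return Symmetric samples x samples ASD matrix with zero diagonal.
#' @export
asd_matrix <- function(gm, variant_ids = NULL) {
  if (!is.null(variant_ids)) gm <- gm[, variant_ids]
  n <- length(gm$samples)
  A1 <- gm$a1; A2 <- gm$a2
  dip <- !is.na(A2)
  lo <- ifelse(dip, pmin(A1, A2), NA_integer_)
  hi <- ifelse(dip, pmax(A1, A2), NA_integer_)
  D <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !is.na(lo[i, ]) & !is.na(lo[j, ])
      if (!any(use)) stopf("samples %s/%s share no diploid locus",
                           gm$samples[i], gm$samples[j])
      x1 <- lo[i, use]; x2 <- hi[i, use]; y1 <- lo[j, use]; y2 <- hi[j, use]
      shared <- ifelse(x1 == x2, (y1 == x1) + (y2 == x1),
                       ((y1 == x1) | (y2 == x1)) + ((y1 == x2) | (y2 == x2)))
      D[i, j] <- D[j, i] <- mean(2 - shared) / 2
    }
  }
  D
}

#' Pairwise repertoire-wide usage correlation matrix
#'
#' Pearson correlation of the per-sample usage-fraction vectors over all
#' retained genes (V, D and J fractions concatenated).
#'
#' @param usage a `usage_matrix` (or bare genes x samples fraction matrix).
#' @return Symmetric samples x samples correlation matrix (unit diagonal).
#' @export
pairwise_usage_correlation <- function(usage) {
  U <- if (inherits(usage, "usage_matrix")) usage$U else usage
  if (nrow(U) < 3) stopf("need at least 3 genes")
  v <- apply(U, 2, stats::var)
  if (any(v == 0)) stopf("zero-variance usage vector: %s",
                         paste(colnames(U)[v == 0], collapse = ", "))
  stats::cor(U)
}

#' Compare usage correlations across allele-sharing-distance bins
#'
#' Unordered sample pairs are binned by ASD quantiles; the mean usage
#' correlation per bin is reported and the correlation distributions of the
#' lowest-ASD and highest-ASD bins are compared with a two-sample
#' Kolmogorov-Smirnov test. Pair non-independence (each sample contributes
#' to many pairs) is ignored by the KS test and reported as a caveat.
#'
#' @param asd samples x samples ASD matrix.
#' @param corr samples x samples usage-correlation matrix (aligned).
#' @param n_bins number of ASD quantile bins (default 4).
#' @return An object of class `similarity_result`: list with `pairs` (pair
#'   table with ASD, correlation and bin), `bin_summary`, `ks` (statistic
#'   and p between extreme bins), and `caveat`.
#' @export
compare_asd_groups <- function(asd, corr, n_bins = 4) {
  stopifnot(all(dim(asd) == dim(corr)), nrow(asd) >= 3)
  if (!identical(rownames(asd), rownames(corr)))
    stopf("ASD and correlation matrices must be sample-aligned")
  ut <- upper.tri(asd)
  pairs <- data.table::data.table(
    s1 = rownames(asd)[row(asd)[ut]], s2 = colnames(asd)[col(asd)[ut]],
    asd = asd[ut], corr = corr[ut])
  if (nrow(pairs) < 2 * n_bins) stopf("fewer pairs than 2 x n_bins")
  br <- stats::quantile(pairs$asd, probs = seq(0, 1, length.out = n_bins + 1))
  if (length(unique(br)) < 3)
    stopf("degenerate ASD distribution: quantile bins collapse")
  br <- unique(br)
  pairs[, bin := cut(asd, breaks = br, include.lowest = TRUE, labels = FALSE)]
  bs <- pairs[, .(n_pairs = .N, mean_asd = mean(asd),
                  mean_corr = mean(corr)), by = bin][order(bin)]
  lo <- pairs[bin == min(bin), corr]
  hi <- pairs[bin == max(bin), corr]
  ks <- suppressWarnings(stats::ks.test(lo, hi))
  structure(list(pairs = pairs, bin_summary = bs,
                 ks = list(statistic = unname(ks$statistic),
                           p = ks$p.value),
                 low_bin_mean = mean(lo), high_bin_mean = mean(hi),
                 caveat = "KS p ignores pair non-independence"),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(paste0("<similarity_result> %d pairs in %d ASD bins\n",
                     "  mean correlation: lowest-ASD bin %.4f vs highest %.4f",
                     " (KS p = %.3g)\n  note: %s\n"),
              nrow(x$pairs), nrow(x$bin_summary),
              x$low_bin_mean, x$high_bin_mean, x$ks$p, x$caveat))
  invisible(x)
}
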