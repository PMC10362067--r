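#' Cross-tabulate coding-allele genotypes against lead-guQTL genotypes
#'
#' Coding-allele genotype classes are unordered pairs (`*01/*03` equals
#' `*03/*01`); hemizygous samples form their own single-allele classes.
#' Samples missing either genotype are dropped, then zero-margin classes
#' are removed.
#'
#' @param allele_gt data.frame with `sample_id`, `allele_1`, `allele_2`
#'   (NA `allele_2` = hemizygous; both NA = missing) for one gene.
#' @param guqtl_gt named character vector of guQTL genotype labels per
#'   sample (e.g. "0/0", "0/1", "1"; NA = missing).
#' @return A contingency table (allele-genotype classes x guQTL classes);
#'   errors if either margin has fewer than 2 classes.
#' @export
allele_guqtl_table <- function(allele_gt, guqtl_gt) {
  df <- as.data.frame(allele_gt)
  lab <- ifelse(is.na(df$allele_1), NA_character_,
                ifelse(is.na(df$allele_2), df$allele_1,
                       paste(pmin(df$allele_1, df$allele_2),
                             pmax(df$allele_1, df$allele_2), sep = "/")))
  gq <- guqtl_gt[df$sample_id]
  use <- !is.na(lab) & !is.na(gq)
  tab <- table(allele_genotype = lab[use], guqtl_genotype = gq[use])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stopf("contingency table needs >= 2 classes on each margin")
  tab
}

#' Fisher exact test of an allele-by-genotype contingency table
#'
#' 2x2 tables use the exact test directly; larger tables use the exact
#' network algorithm when the table total is at most `exact_max`, and
#' otherwise a seeded Monte-Carlo p-value with `B` table draws conditional
#' on the margins. The method used is recorded on the result.
#'
#' @param tab contingency table (matrix), at least 2x2.
#' @param seed seed for the Monte-Carlo fallback.
#' @param exact_max largest table total for the exact path (default 200).
#' @param B Monte-Carlo replicates (default 1e5).
#' @return p-value with attribute `method` ("exact" or "monte-carlo").
#' @export
fisher_assoc <- function(tab, seed = 1, exact_max = 200, B = 1e5) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate margins")
  if (all(dim(tab) == 2) || sum(tab) <= exact_max) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    method <- "exact"
  } else {
    p <- with_seed(child_seed(seed, "fisher"),
                   stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
    method <- "monte-carlo"
  }
  structure(min(p, 1), method = method)
}

#' Apply the novel-allele acceptance filter
#'
#' An allele absent from the database is accepted as novel iff it has an
#' exact match to at least `min_reads` long reads in a single sample, or is
#' identified in at least `min_samples` distinct samples.
#'
#' @param observations data.frame with `sample_id`, `gene`, `allele`,
#'   `reads` (supporting read count) and `exact` (exact-match flag).
#' @param database_alleles character vector of known allele labels
#'   (gene*allele form).
#' @param min_reads single-sample exact-read threshold (default 10).
#' @param min_samples distinct-sample threshold (default 2).
#' @return data.table per candidate allele: support summary and `accepted`.
#' @export
filter_novel_alleles <- function(observations, database_alleles,
                                 min_reads = 10, min_samples = 2) {
  obs <- data.table::as.data.table(observations)
  if (any(obs$reads < 0)) stopf("read counts must be nonnegative")
  obs[, label := paste0(gene, allele)]
  cand <- obs[!label %in% database_alleles]
  out <- cand[, .(
    max_exact_reads = if (any(exact)) max(reads[exact]) else 0L,
    support_samples = data.table::uniqueN(sample_id)),
    by = .(gene, allele, label)]
  out[, accepted := max_exact_reads >= min_reads | support_samples >= min_samples]
  out[]
}
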