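#' Overlap variant positions with feature intervals
#'
#' Variant positions are 1-based; feature intervals are BED-style 0-based
#' half-open. A variant at 1-based position p lies inside [start, end) iff
#' start <= p - 1 < end. Membership per feature class is the union over the
#' class's intervals.
#'
#' @param positions named integer vector (names = variant ids, values =
#'   1-based positions).
#' @param features data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `class`; `chrom` must be a single contig matching the
#'   variants (checked via `chrom` argument when provided).
#' @param chrom optional contig name of the variants; features on other
#'   contigs are ignored.
#' @return Named list (one logical membership vector per feature class).
#' @export
overlap_variants <- function(positions, features, chrom = NULL) {
  features <- as.data.frame(features)
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(features)))
  if (any(features$start >= features$end)) stopf("malformed interval (start >= end)")
  if (!is.null(chrom)) features <- features[features$chrom == chrom, , drop = FALSE]
  v <- GenomicRanges::GRanges("locus", IRanges::IRanges(positions, width = 1))
  out <- list()
  for (cl in unique(features$class)) {
    f <- features[features$class == cl, , drop = FALSE]
    fr <- GenomicRanges::GRanges("locus",
                                 IRanges::IRanges(f$start + 1L, f$end))
    hit <- GenomicRanges::countOverlaps(v, fr) > 0
    names(hit) <- names(positions)
    out[[cl]] <- hit
  }
  out
}

#' One-sided Fisher enrichment of guQTL variants in feature classes
#'
#' For each feature class, builds the 2x2 table
#' \[\[guQTL in, guQTL out\], \[background in, background out\]\] and tests
#' enrichment with a one-sided Fisher exact test (alternative "greater";
#' depletion is never flagged). A Benjamini-Hochberg column across classes
#' is emitted for reference but carries no gate.
#'
#' @param guqtl_ids,background_ids disjoint variant-id sets (background =
#'   tested variants significant for no gene).
#' @param membership named list of logical membership vectors (from
#'   [overlap_variants()]), indexed by variant id.
#' @return data.table with per-class table cells, odds ratio, one-sided p
#'   and BH-adjusted p.
#' @export
fisher_enrichment <- function(guqtl_ids, background_ids, membership) {
  if (!length(guqtl_ids) || !length(background_ids)) stopf("empty variant set")
  if (length(intersect(guqtl_ids, background_ids)))
    stopf("guQTL and background sets must be disjoint")
  rows <- lapply(names(membership), function(cl) {
    m <- membership[[cl]]
    a <- sum(m[guqtl_ids]); b <- length(guqtl_ids) - a
    c_ <- sum(m[background_ids]); d <- length(background_ids) - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    data.table::data.table(class = cl, guqtl_in = a, guqtl_out = b,
                           bg_in = c_, bg_out = d,
                           odds_ratio = if (b * c_ > 0) (a * d) / (b * c_) else Inf,
                           p = ft$p.value)
  })
  out <- data.table::rbindlist(rows)
  out[, p_bh := stats::p.adjust(p, "BH")]
  out
}

#' Intersect significant variants with a GWAS-catalog-style table
#'
#' Retains GWAS rows with association p below `p_max` and reports those
#' matching a significant guQTL variant, joining on variant id first with a
#' position fallback.
#'
#' @param guqtl_ids significant variant ids.
#' @param positions named vector of 1-based positions for `guqtl_ids`.
#' @param gwas data.frame as returned by [read_gwas_table()] (columns
#'   `snp_id`, `position`, `trait`, `p`, `study`).
#' @param p_max GWAS significance cut (default 4e-6; rows with p >= p_max
#'   are dropped).
#' @return data.table of overlaps (variant, trait, study, gwas_p,
#'   matched_by).
#' @export
gwas_overlap <- function(guqtl_ids, positions, gwas, p_max = 4e-6) {
  gw <- data.table::as.data.table(gwas)[p < p_max]
  if (!nrow(gw)) return(data.table::data.table(
    variant = character(), trait = character(), study = character(),
    gwas_p = numeric(), matched_by = character()))
  by_id <- gw[snp_id %in% guqtl_ids]
  out1 <- if (nrow(by_id)) by_id[, .(variant = snp_id, trait, study,
                                     gwas_p = p, matched_by = "id")]
  rest <- gw[!snp_id %in% guqtl_ids]
  pos_map <- positions[guqtl_ids]
  hit <- match(rest$position, pos_map)
  out2 <- rest[!is.na(hit), .(variant = guqtl_ids[hit[!is.na(hit)]], trait,
                              study, gwas_p = p, matched_by = "position")]
  data.table::rbindlist(list(out1, out2))
}
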