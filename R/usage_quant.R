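#' Default gene merge map
#'
#' Gene pairs/groups whose repertoire assignments are combined into a single
#' usage entity because their coding sequences are too similar to
#' distinguish reliably: IGHV3-23/-23D, IGHV3-30/-30-3/-30-5/-33,
#' IGHV1-69/-69D and IGHD4-4/IGHD4-11.
#'
#' @return Named character vector mapping source gene -> merged entity name.
#' @export
default_merge_map <- function() {
  c("IGHV3-23D" = "IGHV3-23",
    "IGHV3-30-3" = "IGHV3-30", "IGHV3-30-5" = "IGHV3-30",
    "IGHV3-33" = "IGHV3-30",
    "IGHV1-69D" = "IGHV1-69",
    "IGHD4-11" = "IGHD4-4")
}

#' Default excluded genes
#'
#' Genes removed from usage analysis: IGHD5-5 (repertoire assignments are
#' ambiguous with IGHD5-18) and IGHV3-16 (no repertoire reads assigned).
#'
#' @return Character vector of gene names.
#' @export
default_exclusions <- function() c("IGHD5-5", "IGHV3-16")

seg_of_gene <- function(g) substr(g, 4, 4)

#' Count clones per (merged) gene and sample
#'
#' Builds the genes x samples clone count matrix C. Each clone contributes 1
#' to exactly one merged gene row per segment class. Assignments to genes
#' deleted from both chromosomes in the sample's genomic data are removed; a
#' clone whose only assignment was such a gene is dropped. Comma-separated
#' multi-assignments are resolved to the single genomically present gene
#' when the deletion data allows it; otherwise the clone is dropped from
#' that segment's counts (policy `"drop"`, the default) or split equally
#' across its candidate genes (policy `"split"`). Excluded genes never
#' appear as rows.
#'
#' @param clones AIRR clone table (data.frame/data.table) with `sample_id`,
#'   `clone_id` and at least one of `v_call`, `d_call`, `j_call`.
#' @param merge_map named vector mapping source gene to merged entity
#'   (default [default_merge_map()]).
#' @param exclusions genes to drop (default [default_exclusions()]).
#' @param deleted_genes named list: sample id -> character vector of genes
#'   with diploid copy number 0 in that sample (raw gene names).
#' @param multi_policy "drop" or "split" for unresolvable multi-assignments.
#' @return An object of class `usage_counts`: list with `C` (genes x samples
#'   count matrix), `segment` (named V/D/J class per gene row) and `dropped`
#'   (per-sample log of removed assignments by reason).
#' @export
count_clones <- function(clones, merge_map = default_merge_map(),
                         exclusions = default_exclusions(),
                         deleted_genes = NULL,
                         multi_policy = c("drop", "split")) {
  multi_policy <- match.arg(multi_policy)
  dt <- data.table::as.data.table(clones)
  if (!all(c("sample_id", "clone_id") %in% names(dt)))
    stopf("clone table needs sample_id and clone_id columns")
  samples <- sort(unique(dt$sample_id))
  del_key <- character(0)
  if (!is.null(deleted_genes) && length(deleted_genes)) {
    del_key <- unlist(lapply(names(deleted_genes), function(s)
      paste(s, deleted_genes[[s]], sep = "\r")))
  }
  drops <- list()
  pieces <- list()
  for (col in intersect(c("v_call", "d_call", "j_call"), names(dt))) {
    calls <- dt[[col]]
    keep_row <- !is.na(calls) & nzchar(calls)
    if (!any(keep_row)) next
    sub <- dt[keep_row, c("sample_id", "clone_id"), with = FALSE]
    calls <- calls[keep_row]
    # single assignments (the vast majority) take a vectorised fast path;
    # only comma-separated multi-assignments need the resolution machinery
    multi_row <- grepl(",", calls, fixed = TRUE)
    apply_rules <- function(genes) {
      if (any(!grepl("^[A-Za-z]", genes)))
        stopf("unparseable gene label in %s", col)
      genes
    }
    g1 <- apply_rules(strip_allele(calls[!multi_row]))
    s1 <- sub$sample_id[!multi_row]
    keep1 <- !(g1 %chin% exclusions)
    if (length(del_key)) keep1 <- keep1 & !(paste(s1, g1, sep = "\r") %chin% del_key)
    hit1 <- keep1 & g1 %chin% names(merge_map)
    g1[hit1] <- merge_map[g1[hit1]]
    tallied <- data.table::data.table(sample_id = s1[keep1], gene = g1[keep1],
                                      w = 1)
    lost_samples <- s1[!keep1]

    if (any(multi_row)) {
      gl <- strsplit(calls[multi_row], ",", fixed = TRUE)
      longm <- data.table::data.table(
        row = rep.int(which(multi_row), lengths(gl)),
        sample_id = rep.int(sub$sample_id[multi_row], lengths(gl)),
        gene = apply_rules(strip_allele(unlist(gl, use.names = FALSE))))
      longm <- unique(longm)
      if (length(del_key))
        longm <- longm[!paste(sample_id, gene, sep = "\r") %chin% del_key]
      longm <- longm[!gene %chin% exclusions]
      hit <- longm$gene %chin% names(merge_map)
      if (any(hit)) {
        data.table::set(longm, which(hit), "gene", merge_map[longm$gene[hit]])
        longm <- unique(longm)
      }
      cntm <- longm[, k := .N, by = row]
      uniq <- longm[k == 1]
      multi <- longm[k > 1]
      tallied <- rbind(tallied, uniq[, .(sample_id, gene, w = 1)])
      if (multi_policy == "split" && nrow(multi)) {
        tallied <- rbind(tallied, multi[, .(sample_id, gene, w = 1 / k)])
      } else if (nrow(multi)) {
        nm <- multi[, .(n = data.table::uniqueN(row)), by = sample_id]
        drops[[paste0(col, "_unresolved_multi")]] <-
          data.frame(sample_id = nm$sample_id, reason = "unresolved_multi",
                     segment = toupper(substr(col, 1, 1)), n = nm$n)
      }
      gone <- setdiff(which(multi_row), longm$row)
      lost_samples <- c(lost_samples, sub$sample_id[gone])
    }
    if (length(lost_samples)) {
      nl <- as.data.frame(table(lost_samples), stringsAsFactors = FALSE)
      drops[[paste0(col, "_no_gene")]] <-
        data.frame(sample_id = nl$lost_samples,
                   reason = "deleted_or_excluded_only",
                   segment = toupper(substr(col, 1, 1)), n = nl$Freq)
    }
    agg <- tallied[, .(count = sum(w)), by = .(sample_id, gene)]
    pieces[[col]] <- agg
  }
  all_counts <- data.table::rbindlist(pieces)
  genes <- sort(unique(all_counts$gene))
  C <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  C[cbind(match(all_counts$gene, genes), match(all_counts$sample_id, samples))] <-
    all_counts$count
  structure(list(C = C,
                 segment = stats::setNames(seg_of_gene(genes), genes),
                 dropped = if (length(drops)) do.call(rbind, unname(drops))
                           else data.frame(sample_id = character(),
                                           reason = character(),
                                           segment = character(), n = integer())),
            class = "usage_counts")
}

#' @export
print.usage_counts <- function(x, ...) {
  cat(sprintf("<usage_counts> %d genes x %d samples (%s); %d dropped assignments\n",
              nrow(x$C), ncol(x$C),
              paste(names(table(x$segment)), table(x$segment), sep = ":",
                    collapse = ", "), sum(x$dropped$n)))
  invisible(x)
}

#' Repertoire quality-control filter
#'
#' Flags samples with fewer than `min_reads` reads (summed duplicate counts)
#' in an isotype, or fewer than `min_clones` clones, for removal from that
#' isotype's usage matrix.
#'
#' @param clones AIRR clone table with `sample_id`, `c_call`,
#'   `duplicate_count` and `clone_id`.
#' @param min_reads minimum reads per isotype (default 100).
#' @param min_clones minimum clones per repertoire (default 200).
#' @return data.frame with per sample x isotype totals and a `keep` flag.
#' @export
qc_filter <- function(clones, min_reads = 100, min_clones = 200) {
  dt <- data.table::as.data.table(clones)
  if (!"duplicate_count" %in% names(dt)) dt$duplicate_count <- 1L
  iso <- function(cc) ifelse(grepl("^IGHM|^IgM", cc), "IgM",
                             ifelse(grepl("^IGHG|^IgG", cc), "IgG", cc))
  dt[, isotype := iso(c_call)]
  qc <- dt[, .(n_reads = sum(duplicate_count),
               n_clones = data.table::uniqueN(clone_id)),
           by = .(sample_id, isotype)]
  qc[, keep := n_reads >= min_reads & n_clones >= min_clones]
  as.data.frame(qc)
}

#' Convert clone counts to class-normalised usage fractions
#'
#' u[g, s] = C[g, s] / sum of C over genes of g's segment class in sample s,
#' so V fractions sum to 1 over V genes, D over D genes and J over J genes.
#'
#' @param counts a `usage_counts` object (or bare genes x samples matrix, in
#'   which case segment classes are parsed from gene names).
#' @param covariates optional data.frame with `sample_id`, `age`,
#'   `platform`, attached to the result.
#' @return An object of class `usage_matrix`: list with `U` (fractions), `C`
#'   (counts), `segment`, `samples`, `covariates` and per-sample `totals`
#'   by class.
#' @export
usage_fractions <- function(counts, covariates = NULL) {
  if (is.matrix(counts)) {
    counts <- structure(list(C = counts,
                             segment = stats::setNames(seg_of_gene(rownames(counts)),
                                                       rownames(counts)),
                             dropped = NULL), class = "usage_counts")
  }
  stopifnot(inherits(counts, "usage_counts"))
  C <- counts$C
  if (any(C < 0)) stopf("clone counts must be nonnegative")
  U <- C
  totals <- list()
  for (sg in unique(counts$segment)) {
    rows <- which(counts$segment == sg)
    tot <- colSums(C[rows, , drop = FALSE])
    if (any(tot == 0))
      stopf("sample(s) with zero %s-segment clones (QC should have removed): %s",
            sg, paste(colnames(C)[tot == 0], collapse = ", "))
    U[rows, ] <- sweep(C[rows, , drop = FALSE], 2, tot, `/`)
    totals[[sg]] <- tot
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates <- covariates[match(colnames(C), covariates$sample_id), ]
    if (anyNA(covariates$sample_id)) stopf("covariates missing for some samples")
  }
  structure(list(U = U, C = C, segment = counts$segment,
                 samples = colnames(C), covariates = covariates,
                 totals = totals), class = "usage_matrix")
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("<usage_matrix> %d genes x %d samples%s\n", nrow(x$U), ncol(x$U),
              if (is.null(x$covariates)) "" else " (with covariates)"))
  invisible(x)
}
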