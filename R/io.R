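# Readers and writers. Variant coordinates are 1-based (VCF convention);
# feature intervals are 0-based half-open (BED convention); the conversion
# lives in overlap_variants() and is tested at the boundaries.

#' Write a genotype matrix as VCF v4.2
#'
#' Diploid calls are written as GT `a/b`, hemizygous calls as haploid GT
#' `a`, missing calls as `./.`. SV alleles are symbolic ALTs; the per-allele
#' gene-to-copy map, span and deleted ranges travel in the custom INFO keys
#' `GCMAP`, `END` and `DELR` (documented in the header), so the matrix
#' round-trips through [read_vcf()] losslessly.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param contig contig name.
#' @param contig_length contig length for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig = "igh_sim", contig_length = 1200000L) {
  v <- gm$variants
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
           "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV span end\">",
           "##INFO=<ID=CSV,Number=1,Type=String,Description=\"Containing SV id\">",
           paste0("##INFO=<ID=GCMAP,Number=1,Type=String,Description=\"Per-allele ",
                  "gene copy map: alleleIndex:gene=copies,... joined by |\">"),
           paste0("##INFO=<ID=DELR,Number=1,Type=String,Description=\"Per-allele ",
                  "deleted ranges: alleleIndex:start-end[~start-end] joined by |\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  rows <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    alleles <- strsplit(v$alleles[j], ",")[[1]]
    if (v$class[j] %in% c("SNV", "INDEL")) {
      ref <- "A"; alt <- paste(rep("G", length(alleles) - 1), collapse = ",")
    } else {
      ref <- "N"
      alt <- paste(sprintf("<%s>", alleles[-1]), collapse = ",")
    }
    info <- sprintf("VC=%s", v$class[j])
    if (!is.na(v$containing_sv[j])) info <- paste0(info, ";CSV=", v$containing_sv[j])
    meta <- gm$sv_meta[[v$id[j]]]
    if (!is.null(meta)) {
      info <- paste0(info, ";END=", meta$span[2])
      gc <- paste(vapply(seq_along(meta$alleles), function(k) {
        cmap <- meta$copy_map[[meta$alleles[k]]]
        paste0(k - 1, ":", paste(names(cmap), cmap, sep = "=", collapse = ","))
      }, ""), collapse = "|")
      info <- paste0(info, ";GCMAP=", gc)
      dr <- meta$deleted_ranges %||% list()
      if (length(dr)) {
        ds <- paste(vapply(names(dr), function(al) {
          k <- match(al, meta$alleles) - 1
          paste0(k, ":", paste(vapply(dr[[al]], function(r)
            paste(r, collapse = "-"), ""), collapse = "~"))
        }, ""), collapse = "|")
        info <- paste0(info, ";DELR=", ds)
      }
    }
    a1 <- gm$a1[, j]; a2 <- gm$a2[, j]
    gt <- ifelse(is.na(a1), "./.",
                 ifelse(is.na(a2), as.character(a1),
                        paste(pmin(a1, a2), pmax(a1, a2), sep = "/")))
    rows[j] <- paste(c(contig, v$position[j], v$id[j], ref, alt, ".", "PASS",
                       info, "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Haploid GT becomes a hemizygous call, `./.` a missing call. Symbolic SV
#' ALTs are parsed together with the custom `GCMAP`/`END`/`DELR` INFO keys
#' written by [write_vcf()]. Rows with malformed GT strings are collected
#' into an error report (attribute `errors`) rather than silently dropped;
#' a missing GT FORMAT field or duplicate variant ids are hard errors.
#'
#' @param path VCF path.
#' @return A `genotype_matrix` (attribute `errors` holds a data.frame of
#'   rejected rows, empty when the file is clean).
#' @export
read_vcf <- function(path) {
  vr <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vr, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vr@gt
  if (nrow(gt_raw) == 0 || !"FORMAT" %in% colnames(gt_raw))
    stopf("VCF has no FORMAT/genotype section")
  if (!all(grepl("^GT", gt_raw[, "FORMAT"]))) stopf("missing GT format field")
  ids <- fix[, "ID"]
  if (anyDuplicated(ids)) stopf("duplicate variant ids in VCF")
  samples <- setdiff(colnames(gt_raw), "FORMAT")
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=[^;]*"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  n <- nrow(fix)
  vclass <- character(n); alleles <- character(n); csv <- character(n)
  span_s <- span_e <- rep(NA_integer_, n)
  sv_meta <- list()
  for (j in seq_len(n)) {
    info <- fix[j, "INFO"]
    vclass[j] <- info_field(info, "VC") %||% "SNV"
    if (is.na(vclass[j])) vclass[j] <- "SNV"
    csv[j] <- info_field(info, "CSV")
    alt <- strsplit(fix[j, "ALT"], ",")[[1]]
    if (all(grepl("^<.*>$", alt))) {
      al_names <- c("REF", gsub("[<>]", "", alt))
      gc <- info_field(info, "GCMAP")
      endv <- info_field(info, "END")
      span_s[j] <- as.integer(fix[j, "POS"])
      span_e[j] <- if (!is.na(endv)) as.integer(endv) else span_s[j]
      meta <- list(id = ids[j], span = c(span_s[j], span_e[j]),
                   alleles = al_names, copy_map = list(), deleted_ranges = list())
      if (!is.na(gc)) {
        for (part in strsplit(gc, "|", fixed = TRUE)[[1]]) {
          k <- as.integer(sub(":.*", "", part)) + 1L
          kv <- strsplit(strsplit(sub("^[0-9]+:", "", part), ",")[[1]], "=")
          meta$copy_map[[al_names[k]]] <-
            stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
        }
      }
      dlr <- info_field(info, "DELR")
      if (!is.na(dlr)) {
        for (part in strsplit(dlr, "|", fixed = TRUE)[[1]]) {
          k <- as.integer(sub(":.*", "", part)) + 1L
          rngs <- strsplit(sub("^[0-9]+:", "", part), "~")[[1]]
          meta$deleted_ranges[[al_names[k]]] <-
            lapply(strsplit(rngs, "-"), as.integer)
        }
      }
      sv_meta[[ids[j]]] <- meta
      alleles[j] <- paste(al_names, collapse = ",")
    } else {
      alleles[j] <- if (length(alt) == 1 && vclass[j] == "SNV") "ref,alt"
                    else paste(c(fix[j, "REF"], alt), collapse = ",")
    }
  }
  a1 <- a2 <- matrix(NA_integer_, length(samples), n)
  errors <- list()
  gt_body <- gt_raw[, samples, drop = FALSE]
  for (j in seq_len(n)) {
    g <- sub(":.*", "", gt_body[j, ])
    mis <- is.na(g) | g %in% c("./.", ".", ".|.")   # vcfR reads ./. as NA
    dip <- !mis & grepl("^[0-9]+[/|][0-9]+$", g)
    hap <- !mis & grepl("^[0-9]+$", g)
    bad <- !(dip | hap | mis)
    if (any(bad)) {
      errors[[ids[j]]] <- data.frame(variant = ids[j], sample = samples[bad],
                                     gt = g[bad], stringsAsFactors = FALSE)
      mis <- mis | bad
    }
    a1[dip, j] <- as.integer(sub("[/|].*", "", g[dip]))
    a2[dip, j] <- as.integer(sub(".*[/|]", "", g[dip]))
    a1[hap, j] <- as.integer(g[hap])
  }
  variants <- data.frame(id = ids, position = as.integer(fix[, "POS"]),
                         class = vclass, alleles = alleles,
                         containing_sv = csv, span_start = span_s,
                         span_end = span_e, stringsAsFactors = FALSE)
  gm <- genotype_matrix(variants, a1, a2, samples = samples, sv_meta = sv_meta)
  attr(gm, "errors") <- if (length(errors)) do.call(rbind, errors)
                        else data.frame(variant = character(),
                                        sample = character(), gt = character())
  gm
}

#' Read an AIRR Rearrangement TSV
#'
#' Requires `sample_id`, `v_call` and `clone_id` columns; rows with an empty
#' `v_call` or `clone_id` are dropped (count recorded in attribute
#' `dropped`); a missing `duplicate_count` column defaults to 1 per row with
#' a warning. Multi-assignment calls (comma-separated) are preserved
#' verbatim for downstream resolution.
#'
#' @param path TSV path.
#' @return A `data.table` of clone records.
#' @export
read_airr <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  for (cc in intersect(c("sequence_id", "sample_id", "c_call", "v_call",
                         "d_call", "j_call", "clone_id"), names(dt)))
    data.table::set(dt, j = cc, value = as.character(dt[[cc]]))
  need <- c("sample_id", "v_call", "clone_id")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stopf("AIRR table missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!"duplicate_count" %in% names(dt)) {
    warning("duplicate_count column absent; defaulting to 1 per row")
    dt[, duplicate_count := 1L]
  }
  ok <- !is.na(dt$v_call) & nzchar(dt$v_call) &
    !is.na(dt$clone_id) & nzchar(dt$clone_id)
  out <- dt[ok]
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Write an AIRR Rearrangement TSV
#' @param clones clone table. @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(clones, path) {
  data.table::fwrite(clones, path, sep = "\t")
  invisible(path)
}

#' Read a sample covariate table (CSV: sample_id, age, platform)
#' @param path CSV path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  cv <- data.table::fread(path, colClasses = list(character = "sample_id"))
  need <- c("sample_id", "age", "platform")
  if (!all(need %in% names(cv)))
    stopf("covariate table must have columns %s", paste(need, collapse = ", "))
  as.data.frame(cv)
}

#' Read a BED feature track
#'
#' Expects at least 4 columns (chrom, start, end, name); the name column
#' carries the feature class / TF label. Malformed lines (non-numeric or
#' inverted coordinates) are rejected with an enumerated error.
#'
#' @param path BED path (plain text, no header).
#' @return data.frame with `chrom`, `start`, `end`, `class`.
#' @export
read_bed_features <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 4) stopf("BED file needs >= 4 columns (chrom, start, end, name)")
  data.table::setnames(dt, 1:4, c("chrom", "start", "end", "class"))
  s <- suppressWarnings(as.numeric(dt$start))
  e <- suppressWarnings(as.numeric(dt$end))
  bad <- which(is.na(s) | is.na(e) | s < 0 | s >= e)
  if (length(bad))
    stopf("malformed BED line(s): %s", paste(bad, collapse = ", "))
  data.frame(chrom = as.character(dt$chrom), start = as.integer(s),
             end = as.integer(e), class = as.character(dt$class),
             stringsAsFactors = FALSE)
}

#' Write a BED feature track
#' @param features data.frame with chrom/start/end/class.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  data.table::fwrite(features[, c("chrom", "start", "end", "class")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a GWAS-catalog-style TSV
#'
#' Column names default to the NHGRI-EBI export headers and are
#' configurable.
#'
#' @param path TSV path.
#' @param snp_col,pos_col,trait_col,p_col,study_col source column names.
#' @return data.frame with `snp_id`, `position`, `trait`, `p`, `study`.
#' @export
read_gwas_table <- function(path, snp_col = "SNPS", pos_col = "CHR_POS",
                            trait_col = "DISEASE/TRAIT", p_col = "P-VALUE",
                            study_col = "STUDY ACCESSION") {
  dt <- data.table::fread(path, sep = "\t")
  need <- c(snp_col, pos_col, trait_col, p_col)
  if (!all(need %in% names(dt)))
    stopf("GWAS table missing column(s): %s",
          paste(setdiff(need, names(dt)), collapse = ", "))
  data.frame(snp_id = as.character(dt[[snp_col]]),
             position = as.integer(dt[[pos_col]]),
             trait = as.character(dt[[trait_col]]),
             p = as.numeric(dt[[p_col]]),
             study = if (study_col %in% names(dt))
               as.character(dt[[study_col]]) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits the genotype VCF, one AIRR Rearrangement TSV per sample (under
#' `airr/`), the covariates CSV, the coding-allele genotype TSV and the
#' ground-truth registry JSON. All files round-trip through the package
#' readers losslessly.
#'
#' @param cohort a `sim_cohort` with clones attached.
#' @param out_dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)
  gm <- as_genotype_matrix(cohort)
  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                covariates = file.path(out_dir, "covariates.csv"),
                alleles = file.path(out_dir, "allele_genotypes.tsv"),
                truth = file.path(out_dir, "ground_truth.json"),
                airr_dir = file.path(out_dir, "airr"))
  write_vcf(gm, paths$vcf, contig = cohort$model$contig,
            contig_length = cohort$model$locus_length)
  data.table::fwrite(cohort$samples, paths$covariates)
  dir.create(paths$airr_dir, showWarnings = FALSE)
  if (!is.null(cohort$clones)) {
    for (s in cohort$samples$sample_id) {
      write_airr(cohort$clones[cohort$clones$sample_id == s],
                 file.path(paths$airr_dir, paste0(s, ".airr.tsv")))
    }
  }
  data.table::fwrite(coding_allele_genotypes(cohort), paths$alleles, sep = "\t")
  tr <- cohort$truth %||% cohort_truth(cohort)
  jsonlite::write_json(list(
    seed = cohort$seed,
    effects = tr$effects,
    expected_leads = tr$expected_leads,
    copy_number = as.data.frame(tr$copy_number)),
    paths$truth, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Coding-allele genotype table of a simulated cohort
#'
#' One row per sample and tagged gene: diploid samples carry two labels,
#' samples with the gene deleted on one haplotype are hemizygous (NA
#' `allele_2`), full deletions are missing (both NA).
#'
#' @param cohort a `sim_cohort`.
#' @return data.frame with `sample_id`, `gene`, `allele_1`, `allele_2`.
#' @export
coding_allele_genotypes <- function(cohort) {
  coding <- cohort$model$coding_alleles
  if (!nrow(coding)) {
    return(data.frame(sample_id = character(), gene = character(),
                      allele_1 = character(), allele_2 = character()))
  }
  cn1 <- hap_copy_matrix(cohort, 1); cn2 <- hap_copy_matrix(cohort, 2)
  out <- list()
  for (i in seq_len(nrow(coding))) {
    g <- coding$gene[i]; tag <- coding$tag_snv[i]
    lab_of <- function(hap, cn) {
      alt <- hap[, tag]
      l <- ifelse(is.na(alt), NA_character_,
                  ifelse(alt == 1L, coding$alt_label[i], coding$ref_label[i]))
      l[cn[, g] == 0] <- NA_character_
      l
    }
    l1 <- lab_of(cohort$snv_hap1, cn1); l2 <- lab_of(cohort$snv_hap2, cn2)
    # normalise: single surviving label in allele_1
    a1 <- ifelse(is.na(l1), l2, l1)
    a2 <- ifelse(is.na(l1), NA_character_, l2)
    out[[g]] <- data.frame(sample_id = cohort$samples$sample_id, gene = g,
                           allele_1 = a1, allele_2 = a2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-sample double-deleted genes from a genotype matrix
#'
#' Uses SV genotypes and their gene-to-copy maps (INFO `GCMAP`) to find, for
#' each sample, the genes with diploid copy number 0; these drive the
#' clone-assignment removal rule in [count_clones()].
#'
#' @param gm a `genotype_matrix` containing SV columns with metadata.
#' @return Named list: sample id -> character vector of deleted genes.
#' @export
deleted_genes_from_genotypes <- function(gm) {
  out <- stats::setNames(vector("list", length(gm$samples)), gm$samples)
  for (meta in gm$sv_meta) {
    j <- match(meta$id, gm$variants$id)
    if (is.na(j)) next
    for (si in seq_along(gm$samples)) {
      k1 <- gm$a1[si, j]; k2 <- gm$a2[si, j]
      if (is.na(k1)) next
      c1 <- meta$copy_map[[meta$alleles[k1 + 1]]]
      c2 <- if (is.na(k2)) 0 else meta$copy_map[[meta$alleles[k2 + 1]]]
      cn <- c1 + c2
      dead <- names(cn)[cn == 0]
      if (length(dead))
        out[[gm$samples[si]]] <- union(out[[gm$samples[si]]], dead)
    }
  }
  out[!vapply(out, is.null, TRUE)]
}
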