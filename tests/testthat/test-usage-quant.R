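mk_clones <- function(sample_id, v_call, d_call = NULL, j_call = NULL) {
  n <- length(v_call)
  data.table::data.table(
    sequence_id = sprintf("q%04d", seq_len(n)), sample_id = sample_id,
    c_call = "IGHM", v_call = v_call,
    d_call = d_call %||% rep(NA_character_, n),
    j_call = j_call %||% rep(NA_character_, n),
    junction_length = 48L, duplicate_count = 1L,
    clone_id = sprintf("c%04d", seq_len(n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("duplicated-gene groups are merged into one row", {
  cl <- mk_clones("S1", c(rep("IGHV3-23*01", 5), rep("IGHV3-23D*01", 3)))
  cnt <- count_clones(cl)
  expect_equal(rownames(cnt$C), "IGHV3-23")
  expect_equal(cnt$C["IGHV3-23", "S1"], 8)
})

test_that("assignments to double-deleted genes are removed", {
  cl <- mk_clones("S1", c(rep("IGHV1-8*01", 4), rep("IGHV1-2*01", 6)))
  cnt <- count_clones(cl, deleted_genes = list(S1 = "IGHV1-8"))
  expect_false("IGHV1-8" %in% rownames(cnt$C))
  expect_equal(cnt$C["IGHV1-2", "S1"], 6)
  expect_equal(cnt$dropped$n[cnt$dropped$reason == "deleted_or_excluded_only"], 4)
})

test_that("multi-assignments resolve by genomic presence or are dropped/split", {
  cl <- mk_clones(rep("S1", 3),
                  c("IGHV1-8*01,IGHV1-2*01",   # resolvable if 1-8 deleted
                    "IGHV1-2*01,IGHV3-7*01",   # unresolvable
                    "IGHV3-7*01"))
  cnt <- count_clones(cl, deleted_genes = list(S1 = "IGHV1-8"))
  expect_equal(cnt$C["IGHV1-2", "S1"], 1)      # resolved to the present gene
  expect_equal(cnt$C["IGHV3-7", "S1"], 1)      # plain single assignment
  expect_equal(cnt$dropped$n[cnt$dropped$reason == "unresolved_multi"], 1)
  cnt2 <- count_clones(cl, deleted_genes = list(S1 = "IGHV1-8"),
                       multi_policy = "split")
  expect_equal(cnt2$C["IGHV1-2", "S1"], 1.5)
  expect_equal(cnt2$C["IGHV3-7", "S1"], 1.5)
})

test_that("excluded genes never appear and multi-maps respect merging", {
  cl <- mk_clones(rep("S1", 2), c("IGHV3-16*01", "IGHV1-2*01"),
                  d_call = c("IGHD5-5*01", "IGHD4-11*01"))
  cnt <- count_clones(cl)
  expect_false(any(c("IGHV3-16", "IGHD5-5") %in% rownames(cnt$C)))
  expect_equal(cnt$C["IGHD4-4", "S1"], 1)      # 4-11 merged into 4-4
  # merged aliases inside one multi-assignment collapse to one candidate
  cl2 <- mk_clones("S1", "IGHV3-23*01,IGHV3-23D*02")
  cnt2 <- count_clones(cl2)
  expect_equal(cnt2$C["IGHV3-23", "S1"], 1)
})

test_that("counts equal a brute-force group-by recount", {
  m <- tiny_model()
  co <- simulate_cohort(m, 12, seed = 31)
  cnt <- count_clones(co$clones)
  mm <- default_merge_map()
  genes <- sub("\\*.*$", "", co$clones$v_call)
  genes <- ifelse(genes %in% names(mm), mm[genes], genes)
  tab <- table(genes, co$clones$sample_id)
  for (g in rownames(tab)) {
    expect_equal(unname(cnt$C[g, colnames(tab)]), unname(as.numeric(tab[g, ])))
  }
})

test_that("QC removes small repertoires per isotype", {
  cl <- rbind(
    mk_clones(rep("S1", 199), rep("IGHV1-2*01", 199)),
    mk_clones(rep("S2", 300), rep("IGHV1-2*01", 300)))
  qc <- qc_filter(cl)
  expect_false(qc$keep[qc$sample_id == "S1"])   # 199 clones < 200
  expect_true(qc$keep[qc$sample_id == "S2"])
  # isotype-specific read rule: 99 IgG reads but a deep IgM repertoire
  igm <- mk_clones(rep("S3", 10000), rep("IGHV1-2*01", 10000))
  igg <- mk_clones(rep("S3", 99), rep("IGHV1-2*01", 99))
  igg$c_call <- "IGHG"
  igg$clone_id <- sprintf("g%04d", seq_len(99))
  qc2 <- qc_filter(rbind(igm, igg))
  expect_true(qc2$keep[qc2$sample_id == "S3" & qc2$isotype == "IgM"])
  expect_false(qc2$keep[qc2$sample_id == "S3" & qc2$isotype == "IgG"])
  # all samples above thresholds: identity
  qc3 <- qc_filter(igm)
  expect_true(all(qc3$keep))
})

test_that("usage fractions divide counts within each segment class", {
  C <- rbind("IGHV1-2" = c(S1 = 50, S2 = 10),
             "IGHV3-7" = c(50, 30),
             "IGHD3-3" = c(7, 5),
             "IGHD4-4" = c(3, 15),
             "IGHJ4" = c(100, 40))
  um <- usage_fractions(C)
  expect_equal(unname(um$U["IGHV1-2", ]), c(0.5, 0.25))
  expect_equal(unname(um$U["IGHJ4", ]), c(1, 1))     # single-gene class
  for (sg in c("V", "D", "J")) {
    rows <- names(um$segment)[um$segment == sg]
    expect_equal(unname(colSums(um$U[rows, , drop = FALSE])), c(1, 1),
                 tolerance = 1e-9)
  }
  expect_equal(um$U["IGHD3-3", "S1"], 0.7)
  bad <- C; bad["IGHD3-3", 2] <- 0; bad["IGHD4-4", 2] <- 0
  expect_error(usage_fractions(bad), "zero")
})

test_that("clone totals are conserved through merging minus logged drops", {
  m <- tiny_model()
  co <- simulate_cohort(m, 10, seed = 13)
  gm <- as_genotype_matrix(co)
  del <- deleted_genes_from_genotypes(gm)
  cnt <- count_clones(co$clones, deleted_genes = del)
  v_dropped <- sum(cnt$dropped$n[cnt$dropped$segment == "V"])
  expect_equal(sum(cnt$C[names(cnt$segment)[cnt$segment == "V"], ]) + v_dropped,
               nrow(co$clones))
})

test_that("QC filtering commutes with fraction computation", {
  m <- tiny_model()
  co <- simulate_cohort(m, 10, seed = 17)
  cnt <- count_clones(co$clones)
  keep <- colnames(cnt$C)[1:6]
  u_then_filter <- usage_fractions(cnt)$U[, keep]
  cnt2 <- cnt; cnt2$C <- cnt$C[, keep]
  filter_then_u <- usage_fractions(cnt2)$U
  expect_equal(u_then_filter, filter_then_u)
})
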