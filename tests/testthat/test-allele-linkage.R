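test_that("the allele-by-guQTL cross-tab reproduces known cell counts", {
  # 62 reference homozygotes: 35 hom *03, 15 het *01/*03, 12 hom *01;
  # 20 alternate homozygotes: all *01/*01
  sample_id <- sprintf("S%03d", 1:82)
  a1 <- c(rep("*03", 35), rep("*01", 15), rep("*01", 12), rep("*01", 20))
  a2 <- c(rep("*03", 35), rep("*03", 15), rep("*01", 12), rep("*01", 20))
  gq <- stats::setNames(c(rep("0/0", 62), rep("1/1", 20)), sample_id)
  tab <- allele_guqtl_table(
    data.frame(sample_id = sample_id, allele_1 = a1, allele_2 = a2), gq)
  expect_equal(tab["*03/*03", "0/0"], 35)
  expect_equal(tab["*01/*03", "0/0"], 15)
  expect_equal(tab["*01/*01", "1/1"], 20)
  expect_false("*03/*03" %in% rownames(tab) && tab["*03/*03", "1/1"] > 0)
  p <- fisher_assoc(tab)
  expect_lt(as.numeric(p), 1e-10)

  # identical allele distributions across genotypes: no association
  gq2 <- stats::setNames(rep(c("0/0", "0/1"), 41), sample_id)
  tab2 <- allele_guqtl_table(
    data.frame(sample_id = sample_id, allele_1 = a1, allele_2 = a2), gq2)
  expect_gt(as.numeric(fisher_assoc(tab2)), 0.5)
})

test_that("cross-tab margins equal per-class sample counts (recount oracle)", {
  set.seed(16)
  for (rep in 1:20) {
    n <- 60
    sample_id <- sprintf("S%03d", seq_len(n))
    alleles <- c("*01", "*02", "*03")
    a1 <- sample(alleles, n, TRUE); a2 <- sample(alleles, n, TRUE)
    hemi <- runif(n) < 0.2
    a2[hemi] <- NA
    gq <- stats::setNames(sample(c("0/0", "0/1", "1/1", NA), n, TRUE,
                                 prob = c(.4, .3, .25, .05)), sample_id)
    df <- data.frame(sample_id = sample_id, allele_1 = a1, allele_2 = a2)
    tab <- tryCatch(allele_guqtl_table(df, gq), error = function(e) NULL)
    if (is.null(tab)) next
    # oracle: recount by explicit loops over unordered labels
    lab <- ifelse(is.na(a2), a1, paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
    for (r in rownames(tab)) for (cl in colnames(tab)) {
      expect_equal(unname(tab[r, cl]),
                   sum(lab == r & !is.na(gq) & gq == cl, na.rm = TRUE))
    }
    expect_equal(unname(colSums(tab)),
                 as.vector(table(gq[!is.na(lab)])[colnames(tab)]))
  }
})

test_that("Fisher association matches enumeration on 2x2 and small RxC", {
  p <- fisher_assoc(matrix(c(10, 0, 0, 10), 2))
  expect_equal(as.numeric(p), oracle_fisher_rxc(matrix(c(10, 0, 0, 10), 2)),
               tolerance = 1e-12)
  # proportional rows: independence is the modal configuration
  expect_equal(as.numeric(fisher_assoc(matrix(c(10, 20, 10, 20), 2))), 1,
               tolerance = 1e-9)
  set.seed(23)
  for (rep in 1:60) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(as.numeric(fisher_assoc(tab)), oracle_fisher_rxc(tab),
                 tolerance = 1e-12)
  }
  for (rep in 1:15) {
    tab <- matrix(rpois(9, 3) + 1, 3)
    expect_equal(as.numeric(fisher_assoc(tab)), oracle_fisher_rxc(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_assoc(matrix(c(5, 0, 7, 0), 2)), "degenerate")
})

test_that("Monte-Carlo p lands within 3 SE of the exact enumeration", {
  set.seed(27)
  tab <- matrix(c(12, 4, 6, 3, 14, 5, 7, 2, 9), 3)
  p_exact <- oracle_fisher_rxc(tab)
  p_mc <- fisher_assoc(tab, seed = 5, exact_max = 10, B = 2e4)
  expect_identical(attr(p_mc, "method"), "monte-carlo")
  se <- sqrt(p_exact * (1 - p_exact) / 2e4)
  expect_lt(abs(as.numeric(p_mc) - p_exact), 3 * se + 1e-4)
  # seeded determinism
  p_mc2 <- fisher_assoc(tab, seed = 5, exact_max = 10, B = 2e4)
  expect_identical(as.numeric(p_mc), as.numeric(p_mc2))
})

test_that("novel-allele acceptance applies the reads-or-samples rule", {
  obs <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4", "S5"),
    gene = "IGHV1-2",
    allele = c("*n1", "*n2", "*n2", "*n3", "*01"),
    reads = c(10L, 3L, 3L, 9L, 50L),
    exact = TRUE)
  res <- filter_novel_alleles(obs, database_alleles = "IGHV1-2*01")
  get <- function(al) res$accepted[res$allele == al]
  expect_true(get("*n1"))    # 10 exact reads in one sample
  expect_true(get("*n2"))    # two samples at 3 reads each
  expect_false(get("*n3"))   # 9 reads, one sample
  expect_false("*01" %in% res$allele)  # known allele is not a candidate
  # monotone: extra support never un-accepts
  obs2 <- rbind(obs, data.frame(sample_id = "S9", gene = "IGHV1-2",
                                allele = "*n3", reads = 1L, exact = TRUE))
  res2 <- filter_novel_alleles(obs2, database_alleles = "IGHV1-2*01")
  expect_true(res2$accepted[res2$allele == "*n3"])
  for (al in res$allele[res$accepted])
    expect_true(res2$accepted[res2$allele == al])
})
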