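# small hand-built genotype matrices
mk_gm <- function(a1, a2, class = "SNV", alleles = "ref,alt", ids = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  ids <- ids %||% paste0("v", seq_len(ncol(a1)))
  genotype_matrix(
    data.frame(id = ids, position = seq_len(ncol(a1)) * 100L,
               class = class, alleles = alleles),
    a1, a2, samples = sprintf("S%02d", seq_len(nrow(a1))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele statistics count hemizygotes as single copies", {
  gm <- mk_gm(rep(0L, 10), rep(1L, 10))
  st <- allele_stats(gm, "v1")
  expect_equal(unname(st$freq), c(0.5, 0.5))
  expect_equal(st$maf, 0.5)
  expect_equal(st$n_genotyped, 10)

  gm <- mk_gm(c(rep(1L, 4), rep(0L, 6)),
              c(rep(NA_integer_, 4), rep(0L, 6)))
  st <- allele_stats(gm, "v1")
  expect_equal(unname(st$counts), c(12, 4))
  expect_equal(unname(st$freq[2]), 4 / 16)
  expect_equal(st$n_genotyped, 10)

  gm <- mk_gm(rep(NA_integer_, 5), rep(NA_integer_, 5))
  st <- allele_stats(gm, "v1")
  expect_equal(st$n_genotyped, 0)
  expect_true(is.na(st$maf))
})

test_that("allele-copy conservation: 2 per diploid plus 1 per hemizygote", {
  set.seed(1)
  for (rep in 1:20) {
    n <- 30
    a1 <- sample(c(0L, 1L, NA), n, TRUE)
    a2 <- ifelse(is.na(a1), NA, sample(c(0L, 1L, NA), n, TRUE))
    gm <- mk_gm(a1, a2)
    st <- allele_stats(gm, "v1")
    dip <- sum(!is.na(gm$a1[, 1]) & !is.na(gm$a2[, 1]))
    hemi <- sum(!is.na(gm$a1[, 1]) & is.na(gm$a2[, 1]))
    expect_identical(sum(st$counts), 2L * dip + hemi)
  }
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  p_het <- hwe_exact_test(0, 100, 0)
  expect_equal(p_het, oracle_hwe(0, 100, 0), tolerance = 1e-12)
  expect_lt(p_het, 1e-6)  # the filter fires on an all-heterozygote locus
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
})

test_that("common-variant filter applies the genotyped/MAF/HWE rules", {
  n <- 100
  a1 <- cbind(c(rep(0L, 39), rep(NA, 61)),      # genotyped in 39 only
              rep(0L, n),                        # MAF exactly 0.05
              rep(0L, n),                        # monomorphic
              c(rep(0L, 50), rep(1L, 50)))       # all hets: HWE fails
  a2 <- cbind(c(rep(1L, 39), rep(NA, 61)),
              c(rep(1L, 10), rep(0L, 90)),
              rep(0L, n),
              c(rep(1L, 50), rep(0L, 50)))
  gm <- mk_gm(a1, a2)
  fc <- filter_common(gm, min_genotyped = 40)
  expect_setequal(fc$matrix$variants$id, "v2")
  expect_equal(fc$log$rule[fc$log$variant == "v1"], "min_genotyped")
  expect_equal(fc$log$rule[fc$log$variant == "v3"], "maf")
  expect_equal(fc$log$rule[fc$log$variant == "v4"], "hwe")
  # idempotent
  fc2 <- filter_common(fc$matrix, min_genotyped = 40)
  expect_identical(fc2$matrix$variants$id, fc$matrix$variants$id)
  expect_equal(nrow(fc2$log), 0)
})

test_that("imputation policies behave and protect homozygous deletions", {
  a1 <- cbind(c(0L, 0L, NA, NA, 0L), c(0L, NA, 0L, 0L, 0L))
  a2 <- cbind(c(0L, 0L, NA, NA, 0L), c(0L, NA, 0L, 0L, 0L))
  gm <- mk_gm(a1, a2)
  expect_identical(impute_missing(gm, "drop"), gm)
  imp <- impute_missing(gm, "frequency", seed = 3)
  expect_true(all(!is.na(imp$a1)))
  expect_true(all(imp$a1 == 0L & imp$a2 == 0L))  # all-hom-ref observed
  imp2 <- impute_missing(gm, "frequency", seed = 3)
  expect_identical(imp, imp2)
  expect_error(impute_missing(gm, "nearest"), "arg")

  # SNV inside an SV: missing calls of deletion homozygotes stay missing
  m <- tiny_model()
  m$svs$DEL1$alleles$freq <- c(0.3, 0.7)
  co <- simulate_haplotypes(m, 60, seed = 8)
  g2 <- as_genotype_matrix(co)
  homdel <- co$sv_hap$DEL1[, 1] == "DEL" & co$sv_hap$DEL1[, 2] == "DEL"
  imp3 <- impute_missing(g2, "frequency", seed = 1)
  expect_true(all(is.na(imp3$a1[homdel, "s01"])))
})

test_that("dosage encoding follows the haploid-doubled policy", {
  expect_equal(encode_dosage(0L, 1L), 1)
  expect_equal(encode_dosage(1L, NA_integer_), 2)
  expect_equal(encode_dosage(0L, NA_integer_), 0)
  expect_equal(encode_dosage(1L, 1L), 2)
  expect_error(encode_dosage(NA_integer_, NA_integer_), "MISSING")
  expect_equal(encode_dosage(c(0L, 1L), c(1L, NA), "categorical"),
               c("0/1", "1"))
})

test_that("LD is a symmetric dosage correlation with unit self-LD", {
  a1 <- cbind(c(0L, 0L, 1L, 0L, 1L, 0L), c(0L, 0L, 1L, 0L, 1L, 0L),
              c(1L, 1L, 0L, 1L, 0L, 1L))
  a2 <- cbind(c(0L, 1L, 1L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L, 1L, 1L),
              c(1L, 0L, 0L, 1L, 0L, 0L))
  gm <- mk_gm(a1, a2)
  expect_equal(compute_ld(gm, "v1", "v2")$r, 1)
  expect_equal(compute_ld(gm, "v1", "v3")$r, -1)  # v3 dosage = 2 - v1
  expect_equal(compute_ld(gm, "v1", "v3")$r2, 1)
  ab <- compute_ld(gm, "v1", "v2"); ba <- compute_ld(gm, "v2", "v1")
  expect_identical(ab$r, ba$r)
  gm0 <- mk_gm(cbind(rep(0L, 6), a1[, 1]), cbind(rep(0L, 6), a2[, 1]))
  expect_warning(ld0 <- compute_ld(gm0, "v1", "v2"), "zero")
  expect_true(is.na(ld0$r))
})

test_that("independent variants have mean r-squared near 1/n", {
  set.seed(7)
  n <- 200; reps <- 400
  r2 <- replicate(reps, {
    x <- stats::rbinom(n, 2, 0.4); y <- stats::rbinom(n, 2, 0.4)
    stats::cor(x, y)^2
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.002)
})

test_that("perfect-LD collapsing equals brute-force transitive closure", {
  # ten copies of one variant collapse to a single effective test
  base <- stats::rbinom(40, 2, 0.5)
  a1 <- matrix(pmin(base, 1L), 40, 10); a2 <- matrix(as.integer(base == 2), 40, 10)
  gm <- mk_gm(a1, a2)
  cl <- collapse_perfect_ld(gm)
  expect_equal(cl$effective_tests, 1)
  expect_length(cl$groups[[1]], 10)

  set.seed(11)
  for (rep in 1:30) {
    n <- 40; nv <- 12
    src <- sample(1:5, nv, replace = TRUE)   # planted duplicate structure
    basis <- matrix(stats::rbinom(n * 5, 2, 0.5), n, 5)
    d <- basis[, src, drop = FALSE]
    a1 <- pmin(d, 1L); a2 <- (d == 2)
    mode(a1) <- "integer"; mode(a2) <- "integer"
    gm <- mk_gm(a1, a2)
    cl <- collapse_perfect_ld(gm)
    r2 <- suppressWarnings(stats::cor(dosage_matrix(gm)))^2
    grp_oracle <- oracle_ld_partition(r2, 1)
    expect_identical(canon_partition(unname(cl$group_of)),
                     canon_partition(grp_oracle))
    # no perfect pair: every variant is its own group
    expect_equal(cl$effective_tests, length(unique(grp_oracle)))
  }
})
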