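test_that("noiseless linear structure is recovered exactly", {
  set.seed(2)
  n <- 120
  dos <- stats::rbinom(n, 2, 0.4)
  platform <- sample(c("A", "B"), n, TRUE)
  age <- round(runif(n, 20, 70))
  y <- 0.05 + 0.01 * dos + 0.002 * (platform == "B")
  names(y) <- sprintf("S%04d", seq_len(n))
  a1 <- as.integer(dos >= 1); a2 <- as.integer(dos == 2)
  cov <- data.frame(sample_id = names(y), age = age, platform = platform)
  res <- associate(y, a1, a2, covariates = cov)
  expect_equal(res$beta, 0.01, tolerance = 1e-10)
  expect_lt(res$p_lm, 1e-200)
})

test_that("fold change is the homozygote-group mean ratio", {
  set.seed(3)
  n <- 90
  dos <- rep(c(0, 1, 2), each = 30)
  y <- c(rep(0.074, 30), rep(0.10, 30), rep(0.13, 30)) + rnorm(n, 0, 1e-6)
  names(y) <- sprintf("S%04d", seq_len(n))
  res <- associate(y, as.integer(dos >= 1), as.integer(dos == 2))
  expect_equal(res$fold_change, 0.13 / 0.074, tolerance = 1e-3)
})

test_that("genotype p-values are uniform under the permutation null", {
  set.seed(9)
  n <- 100
  dos <- stats::rbinom(n, 2, 0.5)
  y <- stats::rnorm(n, 0.1, 0.02)
  names(y) <- sprintf("S%04d", seq_len(n))
  ps <- replicate(400, {
    d <- sample(dos)
    associate(y, as.integer(d >= 1), as.integer(d == 2))$p_lm
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the engine agrees with stats::lm to 1e-8 on random instances", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(40:120, 1)
    dos <- stats::rbinom(n, 2, runif(1, 0.2, 0.8))
    hemi <- runif(n) < 0.15
    a1 <- ifelse(hemi, rbinom(n, 1, 0.5), as.integer(dos >= 1))
    a2 <- ifelse(hemi, NA_integer_, as.integer(dos == 2))
    age <- round(runif(n, 20, 70))
    platform <- sample(c("P1", "P2", "P3"), n, TRUE)
    y <- 0.1 + 0.004 * age / 50 + 0.01 * (platform == "P2") +
      0.005 * encode_dosage(a1, a2) + rnorm(n, 0, 0.02)
    names(y) <- sprintf("S%04d", seq_len(n))
    cov <- data.frame(sample_id = names(y), age = age, platform = platform)
    res <- associate(y, a1, a2, covariates = cov)
    d <- encode_dosage(a1, a2)
    lab <- encode_dosage(a1, a2, "categorical")
    keep <- lab %in% names(table(lab))[table(lab) >= 3]
    df <- data.frame(y = y, d = d, lab = lab, age = age,
                     platform = factor(platform))[keep, ]
    ref <- summary(stats::lm(y ~ d + age + platform, df))
    expect_equal(res$beta, unname(ref$coefficients["d", 1]), tolerance = 1e-8)
    expect_equal(res$p_lm, unname(ref$coefficients["d", 4]), tolerance = 1e-8)
    # ANOVA term p (genotype as categorical, after covariates)
    full <- stats::lm(y ~ age + platform + factor(lab), df)
    redu <- stats::lm(y ~ age + platform, df)
    ref_p <- stats::anova(redu, full)[2, "Pr(>F)"]
    expect_equal(res$p_anova, ref_p, tolerance = 1e-8)
    # adjusted R-squared gained by the genotype term
    r2 <- summary(stats::lm(y ~ d + age + platform, df))$adj.r.squared -
      summary(redu)$adj.r.squared
    expect_equal(res$r2_adj, r2, tolerance = 1e-8)
  }
})

test_that("degenerate inputs are flagged rather than mis-fitted", {
  y <- stats::setNames(runif(20, 0.1, 0.2), sprintf("S%04d", 1:20))
  expect_warning(res <- associate(y, rep(0L, 20), rep(0L, 20)),
                 "constant genotype")
  expect_true(is.na(res$p_lm))
  y2 <- stats::setNames(rep(0.1, 30), sprintf("S%04d", 1:30))
  dos <- stats::rbinom(30, 2, 0.5)
  res2 <- associate(y2, as.integer(dos >= 1), as.integer(dos == 2))
  expect_equal(res2$beta, 0)
  expect_equal(res2$p_lm, 1)
})

test_that("Bonferroni thresholds divide alpha by effective tests", {
  expect_equal(bonferroni_threshold(0.05, 5000), 1e-5)
  expect_equal(bonferroni_threshold(0.05, 5435), 9.2e-6, tolerance = 1e-2)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "effective_tests")
})

test_that("a single perfect association is found and summarised", {
  set.seed(5)
  n <- 80
  dos <- stats::rbinom(n, 2, 0.5)
  ids <- sprintf("S%04d", seq_len(n))
  U <- rbind("IGHV1-2" = 0.2 + 0.05 * dos + rnorm(n, 0, 0.001),
             "IGHV3-7" = 0.8 - 0.05 * dos - rnorm(n, 0, 0.001))
  colnames(U) <- ids
  um <- usage_fractions(U)
  gm <- genotype_matrix(
    data.frame(id = "vx", position = 100L, class = "SNV", alleles = "ref,alt"),
    matrix(as.integer(dos >= 1), ncol = 1), matrix(as.integer(dos == 2), ncol = 1),
    samples = ids)
  fit <- run_guqtl(um, gm)
  expect_equal(fit$effective_tests, 1)
  expect_equal(fit$threshold, 0.05)
  srow <- fit$summaries[which(fit$summaries[["gene"]] == "IGHV1-2"), ]
  expect_identical(srow$lead_variant, "vx")
  expect_equal(srow$n_significant, 1L)
  expect_true(srow$lead_significant)
})

test_that("fitted genotype-group means are monotone for copy-number series", {
  res <- run_default_seed(1)
  expect_true(all(diff(res$cn_means[c("2", "3", "4")]) > 0))
})

test_that("multi-allelic variants gate on ANOVA with categorical classes", {
  set.seed(6)
  n <- 120
  g1 <- sample(0:2, n, TRUE); g2 <- sample(0:2, n, TRUE)
  lab_a1 <- pmin(g1, g2); lab_a2 <- pmax(g1, g2)
  y <- 0.1 + 0.02 * (g1 + g2 == 0) + rnorm(n, 0, 0.005)
  names(y) <- sprintf("S%04d", seq_len(n))
  res <- associate(y, as.integer(lab_a1), as.integer(lab_a2),
                   var_class = "MSV")
  expect_true(is.na(res$p_lm))
  expect_false(is.na(res$p_anova))
  expect_lt(res$p_anova, 1e-6)
})

test_that("conditional scans respect the 50-individual stratum rule", {
  m <- tiny_model()
  co <- simulate_cohort(m, 150, seed = 19)
  gm <- as_genotype_matrix(co)
  fc <- filter_common(gm)
  um <- usage_fractions(count_clones(co$clones), covariates = co$samples)
  fit <- run_guqtl(um, fc$matrix)
  g <- fit$summaries$gene[fit$summaries$lead_significant][1]
  cond <- conditional_scan(fit, g, um, fc$matrix, min_stratum_n = 200)
  expect_equal(nrow(cond$skipped), 2)   # both strata below an extreme rule
  expect_length(cond$strata, 0)
  cond49 <- conditional_scan(fit, g, um, fc$matrix, min_stratum_n = 50)
  for (nm in names(cond49$strata)) {
    expect_gte(cond49$strata[[nm]]$n, 50)
  }
  if (nrow(cond49$skipped)) expect_true(all(cond49$skipped$n < 50))
})

test_that("a stratum with only monomorphic variants yields an empty result", {
  ids <- sprintf("S%04d", 1:60)
  dos_lead <- rep(c(0L, 2L), each = 30)
  # second variant varies only inside the alt stratum
  v2 <- c(rep(0L, 30), rbinom(30, 2, 0.5))
  U <- rbind("IGHV1-2" = runif(60, 0.4, 0.6))
  colnames(U) <- ids
  U <- rbind(U, "IGHV3-7" = 1 - U["IGHV1-2", ])
  um <- usage_fractions(U)
  gm <- genotype_matrix(
    data.frame(id = c("lead", "v2"), position = c(10L, 20L), class = "SNV",
               alleles = "ref,alt"),
    cbind(as.integer(dos_lead >= 1), as.integer(v2 >= 1)),
    cbind(as.integer(dos_lead == 2), as.integer(v2 == 2)), samples = ids)
  fit <- run_guqtl(um, gm)
  cond <- conditional_scan(fit, "IGHV1-2", um, gm, min_stratum_n = 20)
  ref <- cond$strata$ref_hom
  expect_true(is.null(ref$results) ||
                identical(ref$note, "no_polymorphic_variants") ||
                nrow(ref$results[ref$results$significant]) == 0)
  expect_identical(cond$strata$ref_hom$note, "no_polymorphic_variants")
})
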