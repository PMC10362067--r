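test_that("SNVs in one two-haplotype block co-segregate perfectly", {
  m <- one_block_model(n_snvs = 3, hap_freq = 0.4)
  co <- simulate_haplotypes(m, 100, seed = 5)
  gm <- as_genotype_matrix(co)
  for (pair in list(c("s01", "s02"), c("s01", "s03"), c("s02", "s03"))) {
    expect_equal(compute_ld(gm, pair[1], pair[2])$r2, 1)
  }
})

test_that("a fixed deletion makes spanned SNVs missing and genes 0-copy", {
  m <- tiny_model()
  m$svs$DEL1$alleles$freq <- c(0, 1)
  co <- simulate_haplotypes(m, 20, seed = 1)
  gm <- as_genotype_matrix(co)
  expect_true(all(is.na(gm$a1[, c("s01", "s02", "s03")])))
  cn <- gene_copy_number(co)
  expect_true(all(cn[, c("IGHD3-3", "IGHD4-4")] == 0))
})

test_that("SV allele frequencies are recovered within binomial error", {
  m <- tiny_model()
  co <- simulate_haplotypes(m, 2000, seed = 42)
  f <- mean(co$sv_hap$DEL1 == "DEL")
  se <- sqrt(0.3 * 0.7 / (2 * 2000))
  expect_lt(abs(f - 0.3), 3 * se)
})

test_that("haplotype and SV allele draws respect preconditions", {
  m <- tiny_model()
  expect_error(simulate_haplotypes(m, 1, seed = 1), "n_samples")
  bad <- m
  bad$svs$DEL1$alleles$freq <- c(0, 0)
  expect_error(validate_locus_model(bad), "zero-frequency|sum to 1")
})

test_that("diploid copy number equals a brute-force recount from haplotypes", {
  m <- tiny_model()
  co <- simulate_haplotypes(m, 60, seed = 9)
  cn <- gene_copy_number(co)
  # independent recount straight from the allele maps
  for (s in sample(co$samples$sample_id, 10)) {
    si <- match(s, co$samples$sample_id)
    for (g in m$genes$name) {
      expected <- 0
      for (h in 1:2) {
        copies <- 1
        for (sv in m$svs) {
          if (g %in% names(sv$copy_map[[1]])) {
            al <- co$sv_hap[[sv$id]][si, h]
            copies <- sv$copy_map[[al]][[g]]
          }
        }
        expected <- expected + copies
      }
      expect_identical(unname(cn[s, g]), as.integer(expected))
    }
  }
  expect_identical(gene_copy_number(co, co$samples$sample_id[3]),
                   cn[co$samples$sample_id[3], ])
})

test_that("usage probabilities are a normalised additive-by-copy model", {
  m <- tiny_model(noise_sd = 0)
  co <- simulate_haplotypes(m, 80, seed = 3)
  pr <- simulate_usage_probs(co)
  for (seg in names(pr)) {
    expect_equal(unname(rowSums(pr[[seg]])), rep(1, 80), tolerance = 1e-12)
    expect_true(all(pr[[seg]] >= 0))
  }
  cn <- gene_copy_number(co)
  zero <- cn[, "IGHD3-3"] == 0
  if (any(zero)) expect_true(all(pr$D[zero, "IGHD3-3"] == 0))
  # doubling copies doubles the unnormalised weight: compare odds ratios
  # between one- and two-copy carriers of the deletion span
  one <- which(cn[, "IGHD3-3"] == 1 & co$samples$platform ==
                 co$samples$platform[1])
  two <- which(cn[, "IGHD3-3"] == 2 & co$samples$platform ==
                 co$samples$platform[1])
  # weight ratios within a sample expose the unnormalised weights: with no
  # noise, p(3-3)/p(3-9) = CN(3-3) * w(3-3) / (2 * w(3-9))
  if (length(one) && length(two)) {
    expect_equal(pr$D[two[1], "IGHD3-3"] / pr$D[two[1], "IGHD3-9"],
                 2 * pr$D[one[1], "IGHD3-3"] / pr$D[one[1], "IGHD3-9"],
                 tolerance = 1e-10)
  }
})

test_that("a sample with an entire segment class deleted is flagged", {
  m <- tiny_model(noise_sd = 0)
  m$svs$DEL1$copy_map$DEL <- c("IGHD3-3" = 0, "IGHD4-4" = 0)
  m$genes <- m$genes[m$genes$name != "IGHD3-9", ]
  m$baseline_weights <- m$baseline_weights[m$genes$name]
  m$covariate_model$age_slope <- m$covariate_model$age_slope[m$genes$name]
  m$covariate_model$platform_effects <-
    m$covariate_model$platform_effects[m$genes$name, ]
  m$svs$DEL1$alleles$freq <- c(0, 1)
  co <- simulate_haplotypes(m, 5, seed = 2)
  expect_error(simulate_usage_probs(co), "degenerate")
})

test_that("clone sampling is multinomial, conserves totals and is seeded", {
  m <- tiny_model()
  co <- simulate_haplotypes(m, 3, seed = 4)
  cl <- simulate_clones(co, n_clones = 500, seed = 10)
  expect_equal(nrow(cl), 3 * 500)
  expect_true(all(table(cl$sample_id) == 500))
  expect_true(all(cl$duplicate_count >= 1))
  cl2 <- simulate_clones(co, n_clones = 500, seed = 10)
  expect_identical(cl, cl2)
  # empirical fractions within 4 multinomial SEs of the truth at 50k clones
  s <- co$samples$sample_id[1]
  big <- simulate_clones(co, sample_id = s, n_clones = 50000, seed = 7)
  pv <- simulate_usage_probs(co, s)$V
  vg <- table(factor(sub("\\*.*$", "", big$v_call), levels = names(pv)))
  frac <- as.numeric(vg) / 50000
  se <- sqrt(pv * (1 - pv) / 50000)
  expect_true(all(abs(frac - pv) <= 4 * pmax(se, 1e-6)))
})

test_that("regenerating a cohort with the same seed is byte-identical", {
  m <- tiny_model()
  a <- simulate_cohort(m, 25, seed = 77)
  b <- simulate_cohort(m, 25, seed = 77)
  expect_identical(a$snv_hap1, b$snv_hap1)
  expect_identical(a$snv_hap2, b$snv_hap2)
  expect_identical(a$sv_hap, b$sv_hap)
  expect_identical(a$noise, b$noise)
  expect_identical(a$clones, b$clones)
  c_ <- simulate_cohort(m, 25, seed = 78)
  expect_false(identical(a$clones, c_$clones))
})

test_that("SNVs inside heterozygous deletions are hemizygous, never diploid", {
  m <- tiny_model()
  co <- simulate_haplotypes(m, 120, seed = 6)
  gm <- as_genotype_matrix(co)
  del <- co$sv_hap$DEL1 == "DEL"
  het <- xor(del[, 1], del[, 2])
  hom <- del[, 1] & del[, 2]
  for (v in c("s01", "s02", "s03")) {
    j <- match(v, gm$variants$id)
    expect_true(all(is.na(gm$a2[het, j])))   # hemizygous: no second allele
    expect_true(all(!is.na(gm$a1[het, j])))
    expect_true(all(is.na(gm$a1[hom, j])))   # homozygous deletion: missing
  }
})

test_that("default-model LD blocks are tight within and free across", {
  m <- default_locus_model()
  co <- simulate_haplotypes(m, 500, seed = 123)
  gm <- as_genotype_matrix(co)
  free <- m$snvs$id[is.na(m$snvs$containing_sv)]
  d <- dosage_matrix(gm[, free])
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  blk <- m$snvs$block[match(free, m$snvs$id)]
  same <- outer(blk, blk, `==`) & upper.tri(r2)
  diff <- !outer(blk, blk, `==`) & upper.tri(r2)
  expect_gte(mean(r2[same], na.rm = TRUE), 0.8)
  expect_lte(mean(r2[diff], na.rm = TRUE), 0.05)
})

test_that("cohort writing round-trips genotypes, clones and covariates", {
  m <- tiny_model()
  co <- simulate_cohort(m, 15, seed = 21)
  out <- withr::local_tempdir()
  paths <- write_cohort(co, out)
  gm <- as_genotype_matrix(co)
  gm2 <- read_vcf(paths$vcf)
  expect_identical(unname(gm$a1), unname(gm2$a1))
  expect_identical(unname(gm$a2), unname(gm2$a2))
  files <- list.files(paths$airr_dir, full.names = TRUE)
  expect_length(files, 15)
  clones2 <- data.table::rbindlist(lapply(files, read_airr))
  cnt1 <- count_clones(co$clones)
  cnt2 <- count_clones(clones2[order(sample_id, clone_id)])
  expect_equal(cnt1$C, cnt2$C)
  cov2 <- read_covariates(paths$covariates)
  expect_equal(cov2$platform, co$samples$platform)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$seed, 21)
})
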