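test_that("design invariants are enforced", {
  expect_error(cohort_design(c(1), 0.1, 100, c(chr1 = 1e6)), "2 individuals")
  expect_error(cohort_design(c(5, 5), 1.0, 100, c(chr1 = 1e6)), "\\[0, 1\\)")
  expect_error(cohort_design(c(5, 5), 0.1, 100, c(chr1 = 1e6),
                             missing_rate = 0.2), "0.10")
  expect_error(cohort_design(c(5, 5), 0.1, 0, c(chr1 = 1e6)), "n_loci")
  expect_error(cohort_design(c(5, 5), 0.1, 100, c(chr1 = 1e6),
                             mean_depth = 0), "mean_depth")
})

test_that("locus positions are strictly increasing within chromosomes", {
  d <- cohort_design(c(10, 10), 0.1, 500, c(chr1 = 1e6, chr2 = 2e6), seed = 5)
  loci <- draw_population_frequencies(d)$loci
  expect_equal(nrow(loci), 500)
  for (ch in unique(loci$chrom)) {
    p <- loci[chrom == ch, pos]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 1))
  }
})

test_that("F = 0 gives p_k = p exactly; F in (0,1) drifts with mean p", {
  d0 <- cohort_design(c(10, 10, 10), 0, 300, c(chr1 = 1e7), seed = 2)
  fr <- draw_population_frequencies(d0)
  expect_equal(fr$p_k[, 1], fr$p)
  expect_equal(fr$p_k[, 2], fr$p)
  d1 <- cohort_design(c(10, 10), 0.2, 5000, c(chr1 = 1e7), seed = 2)
  fr1 <- draw_population_frequencies(d1)
  expect_false(isTRUE(all.equal(fr1$p_k[, 1], fr1$p)))
  # Beta(p(1-F)/F, (1-p)(1-F)/F) has mean p and variance F p(1-p)
  expect_lt(abs(mean(fr1$p_k[, 1] - fr1$p)), 0.01)
  expect_lt(abs(mean((fr1$p_k[, 1] - fr1$p)^2 / (fr1$p * (1 - fr1$p))) - 0.2),
            0.02)
})

test_that("planted haploblock loci take the given frequencies and rank in the top 1% of per-locus FST", {
  db <- design_with_block(pop_sizes = c(50, 50), fst = 0.05, n_loci = 5000,
                          pop_freqs = c(0.95, 0.05), seed = 21)
  fr <- draw_population_frequencies(db$design, list(db$block))
  idx <- fr$truth[[1]]
  expect_length(idx, 10)
  expect_equal(unname(fr$p_k[idx, 1]), rep(0.95, 10))
  expect_equal(unname(fr$p_k[idx, 2]), rep(0.05, 10))
  geno <- sample_genotypes(fr, db$design, list(db$block))
  per <- wc_fst(geno$dosages, geno$pop_labels)$per_locus
  cutoff <- quantile(per, 0.99, na.rm = TRUE)
  expect_true(all(per[idx] >= cutoff))
})

test_that("genotypes are Binomial(2, p_k): limits and HWE aggregate", {
  # p_k = 0 everywhere -> all dosages 0
  d <- cohort_design(c(6, 6), 0, 50, c(chr1 = 1e6), seed = 3)
  fr <- draw_population_frequencies(d)
  fr$p_k[] <- 0; fr$p[] <- 0
  g <- sample_genotypes(fr, d)
  expect_true(all(g$dosages == 0))
  # HWE: chi-square GOF not rejected in aggregate at alpha = 0.001
  d2 <- cohort_design(c(200, 200), 0.1, 300, c(chr1 = 1e7), seed = 8)
  fr2 <- draw_population_frequencies(d2)
  g2 <- sample_genotypes(fr2, d2)
  pvals <- unlist(lapply(1:2, function(k) {
    cols <- which(g2$pop_labels == paste0("pop", k))
    sapply(seq_len(50), function(i) {
      gg <- g2$dosages[i, cols]
      pk <- fr2$p_k[i, k]
      expct <- 200 * c((1 - pk)^2, 2 * pk * (1 - pk), pk^2)
      obs <- tabulate(gg + 1L, 3L)
      suppressWarnings(chisq.test(obs, p = expct / 200)$p.value)
    })
  }))
  expect_lt(mean(pvals < 0.001), 0.05)
})

test_that("rigid haploblocks give within-block r2 ~ 1 and admixture limits hold", {
  db <- design_with_block(pop_sizes = c(40, 40), fst = 0.05, n_loci = 800,
                          pop_freqs = c(0.5, 0.5), seed = 13,
                          chrom_lengths = c(chr1 = 2e7), missing_rate = 0)
  fr <- draw_population_frequencies(db$design, list(db$block))
  g <- sample_genotypes(fr, db$design, list(db$block))
  idx <- fr$truth[[1]]
  d <- g$dosages[idx, ]
  for (i in 2:length(idx))
    expect_gte(genotype_r2(d[1, ], d[i, ]), 0.95)
  # admixture weight w = 1 reproduces pop a frequencies
  d3 <- cohort_design(c(100, 100), 0.3, 400, c(chr1 = 1e7), seed = 4,
                      admixture = list(pops = c(1, 2), weights = rep(1, 100)))
  fr3 <- draw_population_frequencies(d3)
  g3 <- sample_genotypes(fr3, d3)
  adm <- g3$pop_labels == "admixed"
  pa <- rowMeans(g3$dosages[, g3$pop_labels == "pop1"]) / 2
  pm <- rowMeans(g3$dosages[, adm]) / 2
  expect_gt(cor(pa, pm), 0.9)
  expect_lt(mean(abs(pa - pm)), 0.06)
  expect_lt(max(abs(pa - fr3$p_k[, 1])), 0.2)
})

test_that("read evidence follows the stated AD/DP model", {
  d <- cohort_design(c(20, 20), 0.1, 200, c(chr1 = 1e7), mean_depth = 20,
                     missing_rate = 0, seed = 6)
  fr <- draw_population_frequencies(d)
  g <- sample_genotypes(fr, d)
  ev <- attach_read_evidence(g, fr, d)
  cls_hom_ref <- g$dosages == 0L
  expect_true(all(ev$ad_alt[cls_hom_ref] == 0L))
  expect_true(all(ev$ad_ref[g$dosages == 2L] == 0L))
  expect_true(all(ev$dp >= 1L))
  expect_equal(ev$ad_ref + ev$ad_alt, ev$dp)
  het <- g$dosages == 1L
  expect_lt(abs(mean(ev$ad_alt[het] / ev$dp[het]) - 0.5), 0.02)
  # missing_rate = 0 -> no missing calls
  expect_false(anyNA(ev$dosages))
  # artifact sites skew the het minor fraction to ~0.15
  loci <- fr$loci
  art <- planted_artifact(loci$chrom[5], loci$pos[5])
  fr2 <- draw_population_frequencies(d, list(art))
  g2 <- sample_genotypes(fr2, d, list(art))
  ev2 <- attach_read_evidence(g2, fr2, d, list(art))
  het5 <- g2$dosages[5, ] == 1L
  if (sum(het5) >= 5)
    expect_lt(mean(ev2$ad_alt[5, het5] / ev2$dp[5, het5]), 0.3)
})

test_that("missingness is close to the design rate and recorded as missing", {
  co <- small_cohort(n_loci = 2000, missing_rate = 0.05, seed = 10)
  rate <- mean(is.na(co$dosages))
  expect_lt(abs(rate - 0.05), 0.01)
  expect_true(all(is.na(co$vt$ad[is.na(co$dosages)])))
})

test_that("same seed and design give byte-identical VCF output", {
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(small_cohort(n_loci = 300, seed = 17)$vt, f1)
  write_vcf(small_cohort(n_loci = 300, seed = 17)$vt, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".vcf")
  write_vcf(small_cohort(n_loci = 300, seed = 18)$vt, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("pooled frequency recovers ancestral p (drift-free CI coverage >= 90%)", {
  d <- cohort_design(c(50, 50, 50), 0, 1000, c(chr1 = 1e7), missing_rate = 0,
                     seed = 19)
  fr <- draw_population_frequencies(d)
  g <- sample_genotypes(fr, d)
  n2 <- 2 * ncol(g$dosages)
  phat <- rowSums(g$dosages) / n2
  half <- 1.96 * sqrt(phat * (1 - phat) / n2)
  coverage <- mean(abs(phat - fr$p) <= half)
  expect_gte(coverage, 0.90)
  # with drift the pooled frequency is still unbiased for p on average
  d2 <- cohort_design(c(50, 50, 50), 0.05, 2000, c(chr1 = 1e7),
                      missing_rate = 0, seed = 19)
  fr2 <- draw_population_frequencies(d2)
  g2 <- sample_genotypes(fr2, d2)
  phat2 <- rowSums(g2$dosages) / n2
  expect_lt(abs(mean(phat2 - fr2$p)), 0.01)
})

test_that("truth log matches loci actually altered; sex marker TSV is coherent", {
  db <- design_with_block(seed = 23)
  planted <- list(db$block, planted_sex_marker(2))
  co <- simulate_cohort(db$design, planted)
  idx <- as.integer(strsplit(co$truth_log[feature_kind ==
    "divergent_haploblock", locus_indices], ",")[[1]])
  expect_identical(idx, co$truth[[1]])
  expect_true(all(co$loci$pos[idx] >= db$span[1] &
                  co$loci$pos[idx] <= db$span[2]))
  sheet <- co$sample_sheet
  expect_true(all(sheet[sex == "F", sdY_present] == 0L))
  expect_true(all(sheet[sex == "M" & pop_label == "pop2", sdY_present] == 0L))
  expect_true(all(sheet[sex == "M" & pop_label == "pop1", sdY_present] == 1L))
  paths <- write_cohort(co, file.path(tempdir(), "cohtest"))
  expect_true(all(file.exists(paths)))
  sdy <- data.table::fread(paths["sdy"])
  expect_identical(sdy$sdY_present, sheet$sdY_present)
})
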