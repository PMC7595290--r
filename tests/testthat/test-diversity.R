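test_that("het_stats matches closed-form arithmetic including the genome default", {
  co <- small_cohort(pop_sizes = c(10, 10), n_loci = 500, seed = 3)
  hs <- het_stats(co$vt)
  cls <- genotype_class(co$vt)
  for (j in c(1, 7, 20)) {
    expect_equal(hs$n_het[j], sum(cls[, j] == "het"))
    expect_equal(hs$n_alt_hom[j], sum(cls[, j] == "hom_alt"))
    expect_equal(hs$het_per_kbp[j], hs$n_het[j] / 1927125257 * 1000)
  }
  # worked examples: 1,927,125 hets over the default genome ~ 1.000 /kbp;
  # ratio 100 het / 50 alt-hom = 2
  expect_equal(1927125 / 1927125257 * 1000, 1, tolerance = 1e-4)
  vt <- vt_from_classes(1:150 * 1000,
                        rep(c("het", "hom_alt", "hom_ref"), c(100, 50, 0)))
  one <- het_stats(vt)
  expect_equal(one$n_het, 100)
  expect_equal(one$het_ratio, 2)
  # zero hets and undefined ratio flags
  vt0 <- vt_from_classes(1:10 * 1000, rep("hom_ref", 10))
  z <- het_stats(vt0)
  expect_equal(z$het_per_kbp, 0)
  expect_true(z$ratio_undefined)
  expect_true(is.na(z$het_ratio))
  expect_error(het_stats(vt0, genome_length = 0), "positive")
})

test_that("missing genotypes contribute to neither count", {
  vt <- vt_from_classes(1:6 * 100,
                        c("het", "missing", "hom_alt", "missing", "het",
                          "hom_ref"))
  hs <- het_stats(vt)
  expect_equal(hs$n_het, 2)
  expect_equal(hs$n_alt_hom, 1)
})

test_that("roh_scan: all-het sample yields nothing; all-hom chromosome is one segment", {
  pos <- seq(10000, by = 6000, length.out = 500)  # 3 Mbp, even spacing
  none <- roh_scan(vt_from_classes(pos, rep("het", 500)))
  expect_equal(nrow(none), 0)
  seg <- roh_scan(vt_from_classes(pos, rep("hom_ref", 500)))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, pos[1])
  expect_equal(seg$end, pos[500])
  expect_equal(seg$n_snps, 500L)
  expect_equal(seg$length, pos[500] - pos[1] + 1L)
})

test_that("segment gates are enforced (min SNPs, min length, density, gap)", {
  # 120 hom SNPs over only 600 kbp -> fails the 1,000-kbp length gate
  short <- roh_scan(vt_from_classes(seq(1000, by = 5000, length.out = 120),
                                    rep("hom_ref", 120)))
  expect_equal(nrow(short), 0)
  # 99 SNPs over 2 Mbp -> fails the 100-SNP gate
  few <- roh_scan(vt_from_classes(seq(1000, by = 20000, length.out = 99),
                                  rep("hom_ref", 99)))
  expect_equal(nrow(few), 0)
  # 150 hom SNPs spaced 60 kbp -> fails the 50 kbp/SNP density gate
  sparse <- roh_scan(vt_from_classes(seq(1000, by = 60000, length.out = 150),
                                     rep("hom_ref", 150)))
  expect_equal(nrow(sparse), 0)
  # a > 1 Mbp internal gap splits the run
  pos <- c(seq(1000, by = 8000, length.out = 150),
           seq(3000000, by = 8000, length.out = 150))
  segs <- roh_scan(vt_from_classes(pos, rep("hom_ref", 300)))
  expect_equal(nrow(segs), 2)
  # variant_table sorts on construction, so roh_scan always sees sorted input
  vt <- vt_from_classes(c(5, 1, 9), rep("hom_ref", 3))
  expect_identical(vt$sites$pos, c(1L, 5L, 9L))
})

test_that("a planted 2-Mbp autozygous tract is recovered within 250 kbp", {
  set.seed(17)
  spacing <- 5000
  pos <- seq(spacing, by = spacing, length.out = 1200)  # 6 Mbp chromosome
  tract <- pos >= 2e6 & pos <= 4e6
  cls <- ifelse(tract, "hom_ref",
                sample(c("het", "hom_ref", "hom_alt"), 1200, TRUE,
                       prob = c(0.5, 0.3, 0.2)))
  segs <- roh_scan(vt_from_classes(pos, cls))
  expect_gte(nrow(segs), 1)
  main <- segs[which.max(segs$length)]
  expect_lt(abs(main$start - 2e6), 250000)
  expect_lt(abs(main$end - 4e6), 250000)
  # monotonicity: lengthening the tract never shrinks recovery
  tract2 <- pos >= 1.5e6 & pos <= 4.5e6
  cls2 <- cls; cls2[tract2] <- "hom_ref"
  segs2 <- roh_scan(vt_from_classes(pos, cls2))
  expect_gte(max(segs2$length), max(segs$length))
})

test_that("total_roh sums per sample with zero for segment-free samples", {
  expect_equal(nrow(total_roh(roh_scan(vt_from_classes(1:10 * 100,
                                                       rep("het", 10))))), 0)
  segs <- data.table::data.table(
    sample_id = c("a", "a", "b"), chrom = "c1",
    start = c(1L, 10L, 1L), end = c(2L, 11L, 2L), n_snps = 5L,
    length = c(1500000L, 2500000L, 700000L))
  tot <- total_roh(segs, samples = c("a", "b", "c"))
  expect_equal(tot[sample_id == "a", total_roh_bp], 4.0e6)
  expect_equal(tot[sample_id == "b", total_roh_bp], 7e5)
  expect_equal(tot[sample_id == "c", total_roh_bp], 0)
})

test_that("het_per_kbp and het_ratio correlate across simulated individuals", {
  co <- small_cohort(pop_sizes = c(30, 30), fst = 0.05, n_loci = 2000,
                     seed = 23)
  hs <- het_stats(co$vt)
  rho <- cor(hs$het_per_kbp, hs$het_ratio, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("a fully homozygous genome gives the cohort-maximum ROH total", {
  co <- small_cohort(pop_sizes = c(15, 15), fst = 0.05, n_loci = 3000,
                     chrom_lengths = c(chr1 = 4e7), missing_rate = 0,
                     seed = 31)
  vt <- co$vt
  # doubled-haploid-like sample: force sample 1 homozygous everywhere
  het1 <- !is.na(vt$a1[, 1]) & vt$a1[, 1] != vt$a2[, 1]
  vt$a2[het1, 1] <- vt$a1[het1, 1]
  segs <- roh_scan(vt)
  tot <- total_roh(segs, samples = vt$samples)
  expect_equal(tot[which.max(total_roh_bp), sample_id], vt$samples[1])
  span <- max(vt$sites$pos) - min(vt$sites$pos)
  expect_gt(tot[sample_id == vt$samples[1], total_roh_bp], 0.8 * span)
})
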