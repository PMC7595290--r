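test_that("genotype_r2: identities, symmetry, relabeling invariance, oracle", {
  x <- c(0, 0, 1, 2, 1, 2, 0, 1)
  y <- c(0, 1, 1, 2, 0, 2, 0, 1)
  expect_equal(genotype_r2(x, x), 1)
  expect_equal(genotype_r2(x, 2 - x), 1)  # perfect negative correlation
  expect_equal(genotype_r2(x, y), genotype_r2(y, x))
  expect_equal(genotype_r2(x, y), genotype_r2(2 - x, y))
  # hand Pearson on the spec's 4-genotype example: r2 = 8/11
  expect_equal(genotype_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)), 8 / 11,
               tolerance = 1e-12)
  # oracle identity on random vectors with missingness
  set.seed(5)
  for (i in 1:25) {
    a <- rbinom(30, 2, 0.5); b <- rbinom(30, 2, 0.5)
    a[sample(30, 3)] <- NA
    r <- genotype_r2(a, b)
    if (!is.na(r)) {
      expect_equal(r, oracle_r2(a, b), tolerance = 1e-10)
      expect_gte(r, 0); expect_lte(r, 1 + 1e-12)
    }
  }
  # degenerate inputs
  expect_true(is.na(genotype_r2(c(1, 1, 1, 1), y[1:4])))
  expect_true(is.na(genotype_r2(c(0, 1, NA, NA), c(1, 0, NA, NA))))
})

test_that("chromosome_pairs is complete against brute force and simulation truth", {
  db <- design_with_block(pop_sizes = c(30, 30), fst = 0.05, n_loci = 150,
                          chrom_lengths = c(chr1 = 2e6), n_block = 6,
                          pop_freqs = c(0.5, 0.5), seed = 9, missing_rate = 0)
  co <- simulate_cohort(db$design, list(db$block))
  pairs <- chromosome_pairs(co$vt, "chr1", min_r2 = 0.5)
  # brute force over all pairs with genotype_r2
  d <- to_dosages(co$vt)
  pos <- co$vt$sites$pos
  brute <- list()
  for (i in 1:(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
    r <- genotype_r2(d[i, ], d[j, ])
    if (!is.na(r) && r >= 0.5)
      brute[[length(brute) + 1]] <- c(pos[i], pos[j], round(r, 10))
  }
  bm <- do.call(rbind, brute)
  expect_equal(nrow(pairs), nrow(bm))
  expect_equal(pairs$pos_a, bm[, 1])
  expect_equal(pairs$pos_b, bm[, 2])
  expect_equal(round(pairs$r2, 10), bm[, 3])
  # planted haploblock forms a complete subgraph
  bidx <- co$truth[[1]]
  bpos <- co$loci$pos[bidx]
  sub <- pairs[pos_a %in% bpos & pos_b %in% bpos]
  expect_equal(nrow(sub), choose(length(bpos), 2))
  expect_error(chromosome_pairs(co$vt, "nope"), "unknown chromosome")
})

test_that("single-variant chromosome yields an empty pair list", {
  n <- 10
  vt <- variant_table(
    data.table::data.table(chrom = "chrZ", pos = 50L, ref = "A", alt = "G"),
    sprintf("s%d", 1:n), matrix(0L, 1, n), matrix(rep(0:1, 5), 1, n))
  expect_equal(nrow(chromosome_pairs(vt, "chrZ")), 0)
})

test_that("block_around_lead equals a brute-force member scan and covers the planted span", {
  db <- design_with_block(pop_sizes = c(40, 40), fst = 0.05, n_loci = 300,
                          chrom_lengths = c(chr1 = 5e6), n_block = 8,
                          pop_freqs = c(0.9, 0.1), seed = 13)
  co <- simulate_cohort(db$design, list(db$block))
  bidx <- co$truth[[1]]
  lead <- co$loci$pos[bidx[4]]
  blk <- block_around_lead(co$vt, "chr1", lead, min_r2 = 0.3)
  d <- to_dosages(co$vt)
  li <- which(co$vt$sites$pos == lead)
  want <- which(vapply(seq_len(nrow(d)), function(i)
    isTRUE(genotype_r2(d[li, ], d[i, ]) >= 0.3) || i == li, logical(1)))
  expect_equal(blk$members$pos, sort(co$vt$sites$pos[want]))
  # block span covers >= 90% of the planted span
  planted_span <- db$span[2] - db$span[1]
  covered <- min(blk$end, db$span[2]) - max(blk$start, db$span[1])
  expect_gte(covered / planted_span, 0.9)
  expect_error(block_around_lead(co$vt, "chr1", -1), "not found")
})

test_that("lead with no linked partners returns a singleton block of span 0", {
  set.seed(3)
  n <- 40
  d <- matrix(rbinom(5 * n, 2, 0.5), 5, n)
  a1 <- matrix(0L, 5, n); a2 <- matrix(0L, 5, n)
  a1[d == 2] <- 1L; a2[d >= 1] <- 1L
  vt <- variant_table(
    data.table::data.table(chrom = "c1", pos = c(1e3, 1e5, 2e5, 3e5, 4e5),
                           ref = "A", alt = "G"),
    sprintf("s%d", 1:n), a1, a2)
  blk <- block_around_lead(vt, "c1", 1000, min_r2 = 0.999)
  expect_equal(nrow(blk$members), 1)
  expect_equal(blk$span, 0)
})

test_that("longrange_track counts variants (not pairs) with distant partners", {
  pairs <- data.table::data.table(
    pos_a = c(100L, 100L, 100L, 5000L),
    pos_b = c(500000L, 700000L, 1500000L, 6000L),
    distance = c(499900L, 699900L, 1499900L, 1000L),
    r2 = 0.9)
  tr <- longrange_track(pairs, "c1", 3000000L)
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$end - tr$start + 1L <= 1000000L))
  expect_equal(tr$start, c(1L, 1000001L, 2000001L))
  # window 1: variant at 100 (three distant partners counts once) + 500000 +
  # 700000; window 2: the 1.5 Mbp partner; pair at 1 kbp distance ignored
  expect_equal(tr$count, c(3L, 1L, 0L))
  expect_equal(tr$log_count, log10(c(4, 2, 1)))
  # no distant pairs -> all-zero track
  near <- pairs[4]
  tr0 <- longrange_track(near, "c1", 2000000L)
  expect_true(all(tr0$count == 0))
  # windows tile without overlap
  expect_equal(tr$start[-1], tr$end[-3] + 1L)
})

test_that("two planted distant co-inherited blocks elevate only their windows", {
  d <- cohort_design(c(40, 40), 0.02, 300, c(chr1 = 6e6), missing_rate = 0,
                     seed = 29)
  loci <- draw_population_frequencies(d)$loci
  rows1 <- which(loci$chrom == "chr1" & loci$pos < 1e6)
  rows2 <- which(loci$chrom == "chr1" & loci$pos > 5e6)
  b1 <- planted_haploblock("chr1", loci$pos[rows1[1]],
                           loci$pos[rows1[5]], c(0.5, 0.5))
  co <- simulate_cohort(d, list(b1))
  # copy the block genotypes to a far window to fake co-inheritance
  vt <- co$vt
  src <- co$truth[[1]]
  dst <- rows2[seq_along(src)]
  vt$a1[dst, ] <- vt$a1[src, ]; vt$a2[dst, ] <- vt$a2[src, ]
  pairs <- chromosome_pairs(vt, "chr1", min_r2 = 0.5)
  tr <- longrange_track(pairs, "chr1", 6e6)
  hot <- unique(c((loci$pos[src] - 1L) %/% 1000000L + 1L,
                  (loci$pos[dst] - 1L) %/% 1000000L + 1L))
  expect_true(all(tr$count[hot] >= length(src)))
  expect_true(all(tr$count[-hot] <= 2))
})

test_that("BED export uses 0-based half-open coordinates", {
  tr <- longrange_track(
    data.table::data.table(pos_a = integer(), pos_b = integer(),
                           distance = integer(), r2 = numeric()),
    "c1", 2500000L)
  f <- tempfile(fileext = ".tsv")
  write_track_bed(tr, f)
  bed <- data.table::fread(f)
  expect_equal(bed$start0, tr$start - 1L)
  expect_equal(bed$end, tr$end)
})
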