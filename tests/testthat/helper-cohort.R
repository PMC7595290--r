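# Fixture builders: small cohorts and a hand-enumerable 12-variant toy VCF.

small_cohort <- function(pop_sizes = c(30, 30), fst = 0.1, n_loci = 1000,
                         missing_rate = 0.02, seed = 42, planted = list(),
                         chrom_lengths = c(chr1 = 2e7, chr2 = 2e7), ...) {
  d <- cohort_design(pop_sizes, fst, n_loci, chrom_lengths,
                     missing_rate = missing_rate, seed = seed, ...)
  simulate_cohort(d, planted)
}

# design + planted haploblock covering n_block consecutive loci on chrom;
# relies on locus positions being a deterministic function of the seed
design_with_block <- function(pop_sizes = c(50, 50), fst = 0.05,
                              n_loci = 5000, seed = 1,
                              chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                              chrom = "chr1", n_block = 10,
                              pop_freqs = c(0.8, 0.2), missing_rate = 0.02) {
  design <- cohort_design(pop_sizes, fst, n_loci, chrom_lengths,
                          missing_rate = missing_rate, seed = seed)
  loci <- draw_population_frequencies(design)$loci
  rows <- which(loci$chrom == chrom)
  a <- rows[floor(length(rows) / 2)]
  block <- planted_haploblock(chrom, loci$pos[a], loci$pos[a + n_block - 1],
                              pop_freqs)
  list(design = design, block = block,
       span = c(loci$pos[a], loci$pos[a + n_block - 1]))
}

# single-sample, single-chromosome variant table from a genotype class
# vector ("het", "hom_ref", "hom_alt", "missing") at given positions
vt_from_classes <- function(pos, cls, sample_id = "s1") {
  n <- length(pos)
  a1 <- matrix(NA_integer_, n, 1); a2 <- matrix(NA_integer_, n, 1)
  a1[cls == "hom_ref"] <- 0L; a2[cls == "hom_ref"] <- 0L
  a1[cls == "het"] <- 0L; a2[cls == "het"] <- 1L
  a1[cls == "hom_alt"] <- 1L; a2[cls == "hom_alt"] <- 1L
  variant_table(
    data.table::data.table(chrom = "chr1", pos = as.integer(pos),
                           ref = "A", alt = "G"),
    sample_id, a1, a2)
}

# GT string builders for the toy VCF
gt_col <- function(n, het = integer(), hom_alt = integer(),
                   missing = integer(), alt2_het = integer()) {
  g <- rep("0/0", n)
  g[het] <- "0/1"; g[hom_alt] <- "1/1"; g[missing] <- "./."
  g[alt2_het] <- "0/2"
  g
}

# 12-variant toy VCF over 140 samples exercising every filter rule; the
# expected survivor sets are enumerated by hand in test-acceptance.R
make_toy_vcf <- function(path) {
  n <- 140
  samples <- sprintf("S%03d", 1:n)
  rec <- function(chrom, pos, ref, alt, filter, fmt, calls)
    paste(c(chrom, pos, ".", ref, alt, ".", filter, ".", fmt, calls),
          collapse = "\t")
  with_ad <- function(g, het_ad, het_dp) {
    ifelse(g == "0/1", paste0(g, ":", het_ad, ":", het_dp),
           ifelse(g == "0/0", paste0(g, ":20,0:20"), paste0(g, ":.:.")))
  }
  v8 <- gt_col(n, het = 41:71)
  v8c <- with_ad(v8, "30,30", "60")
  v8c[71] <- "0/1:9,51:60"           # rho = 9/51 ~ 0.176 < 0.2
  v9c <- with_ad(gt_col(n, het = 101:140), "10,40", "50")  # rho = 0.25
  trip <- gt_col(n, het = 71:110, hom_alt = 111:140)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rec("chr1", 1000, "A", "G", "PASS", "GT", gt_col(n, het = 81:120)),
    rec("chr1", 2000, "A", "T,G", "PASS", "GT",
        gt_col(n, het = 1:30, alt2_het = 31:60)),            # non-biallelic
    rec("chr1", 3000, "AT", "A", "PASS", "GT", gt_col(n, het = 1:50)),  # indel
    rec("chr1", 4000, "C", "T", "q10", "GT", gt_col(n, het = 1:50)),    # failed
    rec("chr1", 5000, "G", "A", "PASS", "GT", gt_col(n, het = 1:11)),   # MAF 0.039
    rec("chr1", 6000, "T", "C", "PASS", "GT",
        gt_col(n, missing = 1:15, het = 16:65)),   # call rate 125/140 < 0.9
    rec("chr1", 7000, "A", "C", "PASS", "GT",
        gt_col(n, missing = 1:14, het = 15:54)),   # call rate 0.9 exactly
    rec("chr1", 8000, "G", "T", "PASS", "GT:AD:DP", v8c),    # balance fail
    rec("chr1", 9000, "C", "G", "PASS", "GT:AD:DP", v9c),    # balance pass
    rec("chr2", 1000, "A", "G", "PASS", "GT", trip),
    rec("chr2", 3000, "C", "T", "PASS", "GT", trip),         # r2 = 1 triple
    rec("chr2", 5000, "G", "A", "PASS", "GT", trip))
  writeLines(lines, path)
  path
}

toy_survivors <- list(
  after_basic = c("chr1:1000", "chr1:7000", "chr1:8000", "chr1:9000",
                  "chr2:1000", "chr2:3000", "chr2:5000"),
  after_balance = c("chr1:1000", "chr1:7000", "chr1:9000",
                    "chr2:1000", "chr2:3000", "chr2:5000"),
  after_prune = c("chr1:1000", "chr1:7000", "chr1:9000",
                  "chr2:1000", "chr2:3000"))
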