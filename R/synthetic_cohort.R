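# Balding-Nichols multi-population cohort simulator.
#
# Ancestral frequencies p ~ U(0.05, 0.95); population frequencies drift as
# p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F) so that E[p_k] = p and
# Var[p_k] = F p(1-p). Planted features (rigid divergent haploblocks,
# allele-balance artifact sites, a presence/absence sex marker) are recorded
# in a truth log for downstream power/calibration tests.

#' Describe a simulated cohort
#'
#' @param pop_sizes integer vector, diploid individuals per source population
#' @param fst drift parameter F in `[0, 1)` per population (recycled)
#' @param n_loci total number of biallelic SNP loci
#' @param chrom_lengths named or unnamed base-pair lengths; loci are spread
#'   over chromosomes proportionally to length, positions strictly increasing
#' @param mean_depth expected reads per genotype (Poisson mean, min 1)
#' @param missing_rate i.i.d. genotype missingness in `[0, 0.1]`
#' @param admixture optional `list(pops = c(a, b), weights = w)` appending
#'   `length(w)` admixed individuals whose locus frequencies are
#'   `w * p_a + (1 - w) * p_b`
#' @param seed single integer; all randomness flows from it
#' @return an object of class `cohort_design`
#' @export
cohort_design <- function(pop_sizes, fst, n_loci, chrom_lengths,
                          mean_depth = 30, missing_rate = 0.02,
                          admixture = NULL, seed = 1L) {
  pop_sizes <- as.integer(pop_sizes)
  if (length(pop_sizes) < 1L || sum(pop_sizes) < 2L)
    stopf("need at least 2 individuals in total")
  fst <- rep_len(as.numeric(fst), length(pop_sizes))
  if (any(fst < 0 | fst >= 1))
    stopf("fst must lie in [0, 1); F = 1 gives a degenerate Beta")
  if (n_loci < 1L) stopf("n_loci must be >= 1")
  if (missing_rate < 0 || missing_rate > 0.10)
    stopf("missing_rate must lie in [0, 0.10]; downstream filters assume <= 10%% missingness")
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (!is.null(admixture)) {
    stopifnot(length(admixture$pops) == 2L,
              all(admixture$pops %in% seq_along(pop_sizes)),
              all(admixture$weights >= 0 & admixture$weights <= 1))
  }
  structure(list(pop_sizes = pop_sizes, fst = fst, n_loci = as.integer(n_loci),
                 chrom_lengths = chrom_lengths, mean_depth = mean_depth,
                 missing_rate = missing_rate, admixture = admixture,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Planted cohort features
#'
#' `planted_haploblock()` plants a rigid two-haplotype block (all member loci
#' co-inherited, so within-block genotype r2 is ~1) with per-population
#' haplotype frequencies given verbatim. `planted_artifact()` marks single
#' loci whose heterozygous calls get a skewed minor-read fraction (collapsed
#' paralog mimic). `planted_sex_marker()` declares a presence/absence marker
#' (sdY-like) carried by males, absent in males of one population.
#'
#' @param chrom chromosome name (must exist in the design)
#' @param start,end 1-based inclusive span of the block
#' @param pop_freqs haplotype (or allele) frequency per population, in `[0,1]`
#' @return a `planted_feature` list
#' @export
planted_haploblock <- function(chrom, start, end, pop_freqs) {
  stopifnot(end > start, all(pop_freqs >= 0 & pop_freqs <= 1))
  structure(list(kind = "divergent_haploblock", chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 params = list(pop_freqs = pop_freqs)),
            class = "planted_feature")
}

#' @rdname planted_haploblock
#' @param pos single locus position
#' @param het_skew minor-read fraction for heterozygous calls (default 0.15,
#'   below the 0.2 allele-balance threshold)
#' @export
planted_artifact <- function(chrom, pos, het_skew = 0.15) {
  stopifnot(het_skew > 0, het_skew < 0.5)
  structure(list(kind = "artifact_site", chrom = chrom,
                 start = as.integer(pos), end = as.integer(pos),
                 params = list(het_skew = het_skew)),
            class = "planted_feature")
}

#' @rdname planted_haploblock
#' @param negative_pop population index whose males lack the marker
#' @export
planted_sex_marker <- function(negative_pop) {
  structure(list(kind = "sex_marker", chrom = NA_character_,
                 start = NA_integer_, end = NA_integer_,
                 params = list(negative_pop = as.integer(negative_pop))),
            class = "planted_feature")
}

locus_positions <- function(design) {
  lens <- as.numeric(design$chrom_lengths)
  counts <- pmax(1L, round(design$n_loci * lens / sum(lens)))
  # adjust rounding so counts sum exactly to n_loci
  while (sum(counts) != design$n_loci) {
    i <- if (sum(counts) > design$n_loci) which.max(counts) else which.max(lens)
    counts[i] <- counts[i] + sign(design$n_loci - sum(counts))
  }
  chrom <- rep(names(design$chrom_lengths), counts)
  pos <- unlist(lapply(seq_along(counts), function(i)
    sort(sample.int(lens[i], counts[i]))), use.names = FALSE)
  data.table::data.table(chrom = chrom, pos = as.integer(pos))
}

match_feature_loci <- function(loci, feat) {
  which(loci$chrom == feat$chrom & loci$pos >= feat$start &
          loci$pos <= feat$end)
}

#' Draw ancestral and per-population allele frequencies
#'
#' @param design a [cohort_design()]
#' @param planted list of `planted_feature` objects
#' @param loci optional precomputed locus table (drawn from the design seed
#'   otherwise)
#' @return list with `loci`, `p` (ancestral, length n_loci), `p_k`
#'   (n_loci x n_pops), and `truth` (per-feature locus indices)
#' @export
draw_population_frequencies <- function(design, planted = list(), loci = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    if (is.null(loci)) loci <- locus_positions(design)
    m <- nrow(loci); K <- length(design$pop_sizes)
    p <- runif(m, 0.05, 0.95)
    p_k <- matrix(0, m, K)
    for (k in seq_len(K)) {
      Fk <- design$fst[k]
      p_k[, k] <- if (Fk == 0) p else
        rbeta(m, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
    }
    truth <- list()
    for (j in seq_along(planted)) {
      feat <- planted[[j]]
      if (feat$kind == "sex_marker") { truth[[j]] <- integer(); next }
      idx <- match_feature_loci(loci, feat)
      if (feat$kind == "divergent_haploblock") {
        if (length(idx) < 2L)
          stopf("divergent_haploblock %s:%d-%d spans %d loci; needs >= 2",
                feat$chrom, feat$start, feat$end, length(idx))
        pf <- rep_len(feat$params$pop_freqs, K)
        for (k in seq_len(K)) p_k[idx, k] <- pf[k]
        p[idx] <- mean(pf)
      }
      truth[[j]] <- idx
    }
    list(loci = loci, p = p, p_k = p_k, truth = truth)
  })
}

#' Sample genotype dosages for a cohort
#'
#' Dosage `g ~ Binomial(2, p_k)` per individual and locus; admixed individuals
#' use `p_mix = w p_a + (1 - w) p_b`. Loci inside a planted haploblock are
#' sampled as two block-level haplotypes, so the dosage is constant across the
#' block within an individual.
#'
#' @param freqs output of [draw_population_frequencies()]
#' @param design the same [cohort_design()]
#' @param planted the same planted feature list
#' @return list with `dosages` (loci x individuals), `pop_labels`,
#'   `admix_weights` (NA for unadmixed), `sample_ids`
#' @export
sample_genotypes <- function(freqs, design, planted = list()) {
  with_seed(design$seed + 1L, {
    K <- length(design$pop_sizes)
    pop_of <- rep(seq_len(K), design$pop_sizes)
    w <- rep(NA_real_, length(pop_of))
    if (!is.null(design$admixture)) {
      n_adm <- length(design$admixture$weights)
      pop_of <- c(pop_of, rep(NA_integer_, n_adm))
      w <- c(w, design$admixture$weights)
    }
    n <- length(pop_of); m <- nrow(freqs$loci)
    # per-individual locus frequencies
    pmat <- matrix(0, m, n)
    for (i in seq_len(n)) {
      pmat[, i] <- if (!is.na(pop_of[i])) freqs$p_k[, pop_of[i]] else
        w[i] * freqs$p_k[, design$admixture$pops[1]] +
          (1 - w[i]) * freqs$p_k[, design$admixture$pops[2]]
    }
    block_loci <- integer()
    g <- matrix(rbinom(m * n, 2L, pmat), m, n)
    for (j in seq_along(planted)) {
      feat <- planted[[j]]
      if (feat$kind != "divergent_haploblock") next
      idx <- freqs$truth[[j]]
      # two rigid haplotypes: one block-level dosage per individual
      bg <- rbinom(n, 2L, pmat[idx[1], ])
      g[idx, ] <- matrix(rep(bg, each = length(idx)), length(idx), n)
      block_loci <- c(block_loci, idx)
    }
    labels <- ifelse(is.na(pop_of), "admixed", paste0("pop", pop_of))
    ids <- sprintf("S%03d", seq_len(n))
    list(dosages = g, pop_labels = labels, pop_index = pop_of,
         admix_weights = w, sample_ids = ids, block_loci = block_loci)
  })
}

#' Attach read evidence (AD, DP) and a missingness mask
#'
#' `DP ~ Poisson(mean_depth)` (min 1). Heterozygous calls draw alt reads
#' `Binomial(DP, 0.5)`; at planted artifact sites the alt-read probability is
#' the feature's `het_skew` (default 0.15), yielding balance ratios that fall
#' below the 0.2 filter threshold. Homozygous calls carry zero reads of the
#' other allele. Missing calls are drawn i.i.d. and have AD/DP unset.
#'
#' @param geno output of [sample_genotypes()]
#' @param freqs output of [draw_population_frequencies()]
#' @param design the [cohort_design()]
#' @param planted the planted feature list
#' @return list with `ad_ref`, `ad_alt`, `dp` (integer matrices) and the
#'   updated `dosages` with NA at masked calls
#' @export
attach_read_evidence <- function(geno, freqs, design, planted = list()) {
  with_seed(design$seed + 2L, {
    g <- geno$dosages
    m <- nrow(g); n <- ncol(g)
    dp <- matrix(pmax(1L, rpois(m * n, design$mean_depth)), m, n)
    alt_p <- matrix(0, m, n)
    alt_p[g == 1L] <- 0.5
    for (j in seq_along(planted)) {
      feat <- planted[[j]]
      if (feat$kind != "artifact_site") next
      idx <- freqs$truth[[j]]
      for (i in idx) alt_p[i, g[i, ] == 1L] <- feat$params$het_skew
    }
    ad_alt <- matrix(rbinom(m * n, dp, alt_p), m, n)
    ad_alt[g == 2L] <- dp[g == 2L]
    ad_alt[g == 0L] <- 0L
    ad_ref <- dp - ad_alt
    if (design$missing_rate > 0) {
      mask <- matrix(runif(m * n) < design$missing_rate, m, n)
      g[mask] <- NA_integer_
      ad_ref[mask] <- NA_integer_; ad_alt[mask] <- NA_integer_
      dp[mask] <- NA_integer_
    }
    list(dosages = g, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp)
  })
}

#' Simulate a full cohort
#'
#' Runs frequency drawing, genotype sampling and read-evidence attachment and
#' assembles a truth-annotated cohort: genotypes as a [variant_table()],
#' sample sheet (population label, admixture weight, sex, sdY presence) and a
#' truth log of planted features.
#'
#' @param design a [cohort_design()]
#' @param planted list of `planted_feature` objects
#' @return object of class `sim_cohort` with elements `design`, `loci`, `p`,
#'   `p_k`, `dosages`, `pop_labels`, `sample_sheet`, `planted`, `truth_log`,
#'   `vt`
#' @export
simulate_cohort <- function(design, planted = list()) {
  freqs <- draw_population_frequencies(design, planted)
  geno <- sample_genotypes(freqs, design, planted)
  ev <- attach_read_evidence(geno, freqs, design, planted)
  n <- length(geno$sample_ids)
  # deterministic alternating sexes; sdY present in males unless negated
  sex <- rep(c("M", "F"), length.out = n)
  sdy <- as.integer(sex == "M")
  for (feat in planted) {
    if (feat$kind != "sex_marker") next
    neg <- feat$params$negative_pop
    sdy[sex == "M" & !is.na(geno$pop_index) & geno$pop_index == neg] <- 0L
  }
  sheet <- data.table::data.table(
    sample_id = geno$sample_ids, pop_label = geno$pop_labels,
    admixture_weight = geno$admix_weights, sex = sex, sdY_present = sdy)
  truth <- data.table::rbindlist(lapply(seq_along(planted), function(j) {
    f <- planted[[j]]
    data.table::data.table(feature_kind = f$kind, chrom = f$chrom,
                           start = f$start, end = f$end,
                           locus_indices = paste(freqs$truth[[j]],
                                                 collapse = ","))
  }))
  vt <- cohort_variant_table(freqs$loci, geno$sample_ids, ev)
  structure(list(design = design, loci = freqs$loci, p = freqs$p,
                 p_k = freqs$p_k, dosages = ev$dosages,
                 pop_labels = geno$pop_labels, pop_index = geno$pop_index,
                 admix_weights = geno$admix_weights,
                 sample_sheet = sheet, planted = planted,
                 truth = freqs$truth, truth_log = truth, vt = vt),
            class = "sim_cohort")
}

cohort_variant_table <- function(loci, ids, ev) {
  g <- ev$dosages
  m <- nrow(g); n <- ncol(g)
  a1 <- matrix(NA_integer_, m, n); a2 <- a1
  a1[g == 0L] <- 0L; a2[g == 0L] <- 0L
  a1[g == 1L] <- 0L; a2[g == 1L] <- 1L
  a1[g == 2L] <- 1L; a2[g == 2L] <- 1L
  ad <- matrix(NA_character_, m, n)
  ok <- !is.na(g)
  ad[ok] <- paste0(ev$ad_ref[ok], ",", ev$ad_alt[ok])
  # alternating REF/ALT bases keep records syntactically valid SNPs
  sites <- data.table::data.table(
    chrom = loci$chrom, pos = loci$pos, id = ".",
    ref = rep_len(c("A", "C"), m), alt = rep_len(c("G", "T"), m),
    qual = ".", filter = "PASS", info = ".")
  variant_table(sites, ids, a1, a2, ad = ad, dp = ev$dp)
}

#' Write cohort artifacts to disk
#'
#' Emits `<prefix>.vcf` (VCF v4.2), `<prefix>.samples.tsv`,
#' `<prefix>.truth.tsv`, and `<prefix>.sdY.tsv` (presence/absence table).
#'
#' @param cohort a `sim_cohort`
#' @param prefix output path prefix
#' @return named character vector of written paths
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- c(vcf = paste0(prefix, ".vcf"),
             samples = paste0(prefix, ".samples.tsv"),
             truth = paste0(prefix, ".truth.tsv"),
             sdy = paste0(prefix, ".sdY.tsv"))
  write_vcf(cohort$vt, paths["vcf"])
  data.table::fwrite(cohort$sample_sheet, paths["samples"], sep = "\t")
  tl <- if (nrow(cohort$truth_log %||% data.table::data.table()))
    cohort$truth_log else
    data.table::data.table(feature_kind = character(), chrom = character(),
                           start = integer(), end = integer(),
                           locus_indices = character())
  data.table::fwrite(tl, paths["truth"], sep = "\t")
  data.table::fwrite(cohort$sample_sheet[, .(sample_id, sdY_present)],
                     paths["sdy"], sep = "\t")
  paths
}

#' Weir-Cockerham FST from dosages and population labels
#'
#' Two-level ratio-of-averages estimator (variance components a, b, c summed
#' over loci) for biallelic dosage data; also returns per-locus
#' `a / (a + b + c)` for ranking.
#'
#' @param dosages loci x individuals matrix in 0/1/2 (NA allowed)
#' @param labels population label per individual (>= 2 populations)
#' @return list with `fst` (global) and `per_locus`
#' @export
wc_fst <- function(dosages, labels) {
  labels <- as.factor(labels)
  r <- nlevels(labels)
  if (r < 2L) stopf("wc_fst needs >= 2 populations")
  idx <- split(seq_along(labels), labels)
  m <- nrow(dosages)
  n_i <- sapply(idx, function(ii) rowSums(!is.na(dosages[, ii, drop = FALSE])))
  p_i <- sapply(idx, function(ii)
    rowSums(dosages[, ii, drop = FALSE], na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(idx, function(ii)
    rowSums(dosages[, ii, drop = FALSE] == 1L, na.rm = TRUE)) / n_i
  nbar <- rowMeans(n_i)
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  per_locus <- a / (a + b + cc)
  keep <- is.finite(a) & is.finite(b) & is.finite(cc)
  list(fst = sum(a[keep]) / sum((a + b + cc)[keep]), per_locus = per_locus)
}
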