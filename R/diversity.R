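# Per-individual genomic diversity: heterozygosity metrics and runs of
# homozygosity (PLINK 1.9 --homozyg defaults, emulated).

#' Per-individual heterozygosity statistics
#'
#' Counts heterozygous and homozygous-alternative genotypes per sample over
#' all records (missing calls contribute to neither count) and derives
#' `het_per_kbp = n_het / genome_length * 1000` and
#' `het_ratio = n_het / n_alt_hom`. The default genome length is the sockeye
#' salmon assembly total (1,927,125,257 bp). `het_ratio` is NA (flagged) when
#' `n_alt_hom = 0`.
#'
#' @param vt a [variant_table()]
#' @param genome_length total nucleotides in the genome (default
#'   1,927,125,257)
#' @return data.table: sample_id, n_het, n_alt_hom, het_per_kbp, het_ratio,
#'   ratio_undefined
#' @export
het_stats <- function(vt, genome_length = 1927125257) {
  if (genome_length <= 0) stopf("genome_length must be positive")
  cls <- genotype_class(vt)
  n_het <- as.integer(colSums(cls == "het"))
  n_alt_hom <- as.integer(colSums(cls == "hom_alt"))
  data.table::data.table(
    sample_id = vt$samples,
    n_het = n_het, n_alt_hom = n_alt_hom,
    het_per_kbp = n_het / genome_length * 1000,
    het_ratio = ifelse(n_alt_hom > 0L, n_het / n_alt_hom, NA_real_),
    ratio_undefined = n_alt_hom == 0L)
}

#' Default ROH parameters (PLINK 1.9 --homozyg defaults)
#'
#' Window of 50 SNPs allowing at most 1 heterozygote and 5 missing calls; a
#' SNP joins a run when at least 5% of the windows covering it pass; final
#' segments need >= 100 SNPs, >= 1,000 kbp, density <= 50 kbp/SNP and no
#' internal gap > 1,000 kbp.
#'
#' @return named list of parameters
#' @export
roh_params <- function() {
  list(window_snp = 50L, window_het = 1L, window_missing = 5L,
       hit_frac = 0.05, min_snp = 100L, min_length_kb = 1000,
       max_density_kb_per_snp = 50, max_gap_kb = 1000)
}

roh_one_sample <- function(pos, cls, prm) {
  L <- length(pos)
  w <- prm$window_snp
  segs <- data.table::data.table(start = integer(), end = integer(),
                                 n_snps = integer(), length = integer())
  if (L < prm$min_snp) return(segs)
  het <- cumsum(c(0L, cls == "het"))
  mis <- cumsum(c(0L, cls == "missing"))
  nw <- L - w + 1L
  if (nw < 1L) return(segs)
  i <- seq_len(nw)
  pass <- (het[i + w] - het[i]) <= prm$window_het &
    (mis[i + w] - mis[i]) <= prm$window_missing
  cp <- cumsum(c(0L, pass))
  # windows covering SNP j: indices max(1, j - w + 1) .. min(j, nw)
  j <- seq_len(L)
  lo <- pmax(1L, j - w + 1L); hi <- pmin(j, nw)
  n_pass <- cp[hi + 1L] - cp[lo]
  frac <- n_pass / (hi - lo + 1L)
  flagged <- frac >= prm$hit_frac
  if (!any(flagged)) return(segs)
  # maximal runs of flagged SNPs, split at gaps > max_gap
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    cut <- a + which(diff(pos[a:b]) > prm$max_gap_kb * 1000)
    bounds <- c(a, cut, b + 1L)
    for (s in seq_len(length(bounds) - 1L)) {
      aa <- bounds[s]; bb <- bounds[s + 1L] - 1L
      n <- bb - aa + 1L
      len <- pos[bb] - pos[aa] + 1L
      if (n >= prm$min_snp && len >= prm$min_length_kb * 1000 &&
          len / n <= prm$max_density_kb_per_snp * 1000)
        segs <- rbind(segs, data.table::data.table(
          start = pos[aa], end = pos[bb], n_snps = n, length = len))
    }
  }
  segs
}

#' Runs-of-homozygosity scan
#'
#' Sliding-window ROH detection per sample and chromosome with PLINK-default
#' parameters (see [roh_params()]); an emulation of `--homozyg`, with run-edge
#' tie-breaking as implemented in [roh_one_sample] (runs are maximal stretches
#' of SNPs whose covering-window pass fraction meets `hit_frac`).
#'
#' @param vt a biallelic [variant_table()], position-sorted
#' @param params parameter list, see [roh_params()]
#' @return data.table: sample_id, chrom, start, end, n_snps, length
#' @export
roh_scan <- function(vt, params = roh_params()) {
  cls <- genotype_class(vt)
  out <- list()
  for (chr in unique(vt$sites$chrom)) {
    rows <- which(vt$sites$chrom == chr)
    pos <- vt$sites$pos[rows]
    if (is.unsorted(pos)) stopf("unsorted positions on %s", chr)
    for (s in seq_along(vt$samples)) {
      segs <- roh_one_sample(pos, cls[rows, s], roh_params_check(params))
      if (nrow(segs))
        out[[length(out) + 1L]] <- data.table::data.table(
          sample_id = vt$samples[s], chrom = chr, segs)
    }
  }
  if (!length(out))
    return(data.table::data.table(sample_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  n_snps = integer(), length = integer()))
  data.table::rbindlist(out)
}

roh_params_check <- function(p) {
  d <- roh_params()
  for (nm in names(d)) if (is.null(p[[nm]])) p[[nm]] <- d[[nm]]
  p
}

#' Total ROH length per sample
#'
#' @param segments output of [roh_scan()]
#' @param samples optional sample ids to include with zero totals
#' @return data.table: sample_id, total_roh_bp
#' @export
total_roh <- function(segments, samples = NULL) {
  tot <- if (nrow(segments))
    segments[, .(total_roh_bp = sum(as.numeric(length))), by = sample_id]
  else data.table::data.table(sample_id = character(), total_roh_bp = numeric())
  if (!is.null(samples)) {
    base <- data.table::data.table(sample_id = samples, total_roh_bp = 0)
    base[tot, total_roh_bp := i.total_roh_bp, on = "sample_id"]
    tot <- base
  }
  tot[]
}
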