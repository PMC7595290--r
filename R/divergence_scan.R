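# Eigenvector divergence scan: per-variant OLS of a quantitative score
# (typically a PC score, or an admixture ancestry value) on genotype dosage,
# genomic-control inflation correction, Bonferroni significance, and
# proximity-cluster peak calling.

#' Per-variant regression of a score on dosage
#'
#' Ordinary least squares `score ~ a + b * dosage` per variant over called
#' individuals; `chi2 = (b / se)^2` is referred to a chi-square with 1 df.
#' Variants monomorphic among called individuals, or with fewer than 3 called
#' individuals, have undefined statistics and are excluded from the count of
#' variants interrogated (`m`).
#'
#' @param dosages variants x individuals matrix in 0/1/2 (NA allowed)
#' @param score finite numeric score per individual
#' @param chrom,pos optional per-variant coordinates carried into the result
#'   (taken from the matrix attributes set by [to_dosages()] if present)
#' @return data.table of class `scan_result`: chrom, pos, beta, se, chi2,
#'   p_raw, n_used, valid; attributes `m` (valid variants)
#' @export
eigen_scan <- function(dosages, score, chrom = NULL, pos = NULL) {
  if (length(score) != ncol(dosages))
    stopf("score length %d != %d individuals", length(score), ncol(dosages))
  if (any(!is.finite(score))) stopf("score must be finite for all individuals")
  chrom <- chrom %||% attr(dosages, "chrom") %||% rep(NA_character_, nrow(dosages))
  pos <- pos %||% attr(dosages, "pos") %||% rep(NA_integer_, nrow(dosages))
  g <- dosages
  storage.mode(g) <- "double"
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0
  n_c <- rowSums(obs)
  sx <- rowSums(g0)
  sxx <- rowSums(g0^2)
  sy <- as.vector(obs %*% score)
  syy <- as.vector(obs %*% score^2)
  sxy <- as.vector(g0 %*% score)
  # centered sums over called individuals
  cxx <- sxx - sx^2 / n_c
  cxy <- sxy - sx * sy / n_c
  cyy <- syy - sy^2 / n_c
  valid <- n_c >= 3L & cxx > 1e-12
  beta <- se <- chi2 <- p_raw <- rep(NA_real_, nrow(g))
  beta[valid] <- cxy[valid] / cxx[valid]
  rss <- pmax(cyy[valid] - beta[valid] * cxy[valid], 0)
  s2 <- rss / (n_c[valid] - 2L)
  se[valid] <- sqrt(s2 / cxx[valid])
  ch <- (beta[valid] / se[valid])^2
  # se -> 0: a perfect fit (beta != 0) is capped; a constant score (beta = 0,
  # se = 0, 0/0) carries no signal at all
  nf <- !is.finite(ch)
  ch[nf] <- ifelse(abs(beta[valid][nf]) > 0, 1e10, 0)
  chi2[valid] <- ch
  p_raw[valid] <- pmax(pchisq(chi2[valid], 1L, lower.tail = FALSE),
                       .Machine$double.xmin)
  res <- data.table::data.table(chrom = chrom, pos = pos, beta = beta,
                                se = se, chi2 = chi2, p_raw = p_raw,
                                n_used = n_c, valid = valid)
  data.table::setattr(res, "m", sum(valid))
  data.table::setattr(res, "class", c("scan_result", class(res)))
  res[]
}

#' Genomic inflation factor
#'
#' `lambda_gc = median(chi2) / 0.4549364` (the median of a chi-square with
#' 1 df), floored at 1e-6.
#'
#' @param chi2s finite chi-square statistics (NA dropped)
#' @return lambda
#' @export
genomic_inflation_factor <- function(chi2s) {
  chi2s <- chi2s[is.finite(chi2s)]
  if (!length(chi2s)) stopf("no finite chi-square statistics")
  max(median(chi2s) / CHI2_1_MEDIAN, 1e-6)
}

#' Apply genomic control and Bonferroni significance
#'
#' Divides each statistic by `lambda_gc`, recomputes `p_adj` from the
#' chi-square with 1 df, and flags variants with
#' `p_adj < alpha / m` (Bonferroni over the `m` variants interrogated).
#'
#' @param scan a `scan_result` from [eigen_scan()]
#' @param alpha family-wise significance level (default 0.01)
#' @param lambda optional precomputed inflation factor
#' @return the scan with columns `chi2_adj`, `p_adj`, `significant` added and
#'   attributes `lambda`, `alpha`, `threshold`
#' @export
significant_set <- function(scan, alpha = 0.01, lambda = NULL) {
  m <- attr(scan, "m")
  if (is.null(m) || m == 0L) stopf("no valid variants interrogated (m = 0)")
  lambda <- lambda %||% genomic_inflation_factor(scan$chi2)
  scan[, chi2_adj := chi2 / lambda]
  scan[, p_adj := pmax(pchisq(chi2_adj, 1L, lower.tail = FALSE),
                       .Machine$double.xmin)]
  thr <- alpha / m
  scan[, significant := !is.na(p_adj) & p_adj < thr]
  data.table::setattr(scan, "lambda", lambda)
  data.table::setattr(scan, "alpha", alpha)
  data.table::setattr(scan, "threshold", thr)
  scan[]
}

#' Cluster significant variants into peaks
#'
#' Chains consecutive significant variants on a chromosome whenever the gap
#' between neighbours is at most `max_gap`; chains with at least `min_count`
#' members become peaks. The lead variant is the member with the lowest
#' adjusted p-value.
#'
#' @param sig data.table with chrom, pos and (optionally) p_adj for the
#'   significant variants only
#' @param min_count minimum member count per peak (default 5)
#' @param max_gap maximum between-neighbour gap in bp (default 100000)
#' @return data.table of peaks: chrom, start, end, n_sig, lead_pos, lead_p
#' @export
call_peaks <- function(sig, min_count = 5L, max_gap = 100000L) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_sig = integer(),
                                  lead_pos = integer(), lead_p = numeric())
  if (nrow(sig) == 0L) return(empty)
  sig <- data.table::as.data.table(sig)
  if (is.null(sig$p_adj)) sig[, p_adj := NA_real_]
  data.table::setorder(sig, chrom, pos)
  sig[, gap := c(Inf, diff(pos)), by = chrom]
  sig[, chain := cumsum(gap > max_gap)]
  peaks <- sig[, {
    lead <- if (all(is.na(p_adj))) which.min(pos) else which.min(p_adj)
    .(start = min(pos), end = max(pos), n_sig = .N,
      lead_pos = pos[lead], lead_p = p_adj[lead])
  }, by = .(chrom, chain)]
  peaks <- peaks[n_sig >= min_count][, chain := NULL]
  if (nrow(peaks) == 0L) return(empty)
  peaks[]
}

#' End-to-end divergence scan
#'
#' [eigen_scan()] + [genomic_inflation_factor()] + [significant_set()] +
#' [call_peaks()].
#'
#' @inheritParams eigen_scan
#' @inheritParams significant_set
#' @inheritParams call_peaks
#' @return list(scan, lambda, peaks)
#' @export
run_divergence_scan <- function(dosages, score, alpha = 0.01, min_count = 5L,
                                max_gap = 100000L) {
  scan <- eigen_scan(dosages, score)
  scan <- significant_set(scan, alpha = alpha)
  peaks <- call_peaks(scan[significant == TRUE, .(chrom, pos, p_adj)],
                      min_count = min_count, max_gap = max_gap)
  list(scan = scan, lambda = attr(scan, "lambda"), peaks = peaks)
}
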