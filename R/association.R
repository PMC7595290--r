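# Case/control association: per-variant logistic regression with structure
# covariates and a genome-wide max-statistic permutation threshold.

#' Logistic-regression association scan
#'
#' Per variant, fits `trait ~ intercept + covariates + dosage` by iteratively
#' reweighted least squares and reports the Wald test on the dosage term.
#' Non-convergent and (quasi-)separated fits are flagged, not silently
#' dropped: because the Wald statistic degenerates under separation
#' (Hauck-Donner), flagged variants get a Rao score test instead (column
#' `test` says which was used). Flagged variants are excluded from peak
#' calling.
#'
#' @param dosages variants x individuals matrix in 0/1/2 (NA allowed)
#' @param trait values in 0/1 (NA allowed; those individuals are dropped)
#' @param covariates optional individuals x q numeric matrix (intercept added
#'   internally; must be full rank with the intercept)
#' @return data.table of class `assoc_result`: chrom, pos, beta, se, chi2, p,
#'   converged, flagged
#' @export
logistic_scan <- function(dosages, trait, covariates = NULL) {
  trait <- as.numeric(trait)
  keep <- !is.na(trait)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & complete.cases(covariates)
  }
  y <- trait[keep]
  if (!all(y %in% c(0, 1))) stopf("trait must be binary 0/1")
  if (length(unique(y)) < 2L)
    stopf("trait is constant among non-missing individuals")
  C <- cbind(intercept = rep(1, length(y)), if (!is.null(covariates))
    covariates[keep, , drop = FALSE])
  if (qr(C)$rank < ncol(C))
    stopf("covariate matrix is rank-deficient with the intercept")
  G <- t(dosages[, keep, drop = FALSE])
  storage.mode(G) <- "double"
  fit <- logistic_scan_cpp(C, G, y)
  fit <- lapply(fit, as.vector)
  chi2 <- (fit$beta / fit$se)^2
  p <- pmax(pchisq(chi2, 1L, lower.tail = FALSE), .Machine$double.xmin)
  res <- data.table::data.table(
    chrom = attr(dosages, "chrom") %||% rep(NA_character_, nrow(dosages)),
    pos = attr(dosages, "pos") %||% rep(NA_integer_, nrow(dosages)),
    beta = fit$beta, se = fit$se, chi2 = chi2, p = p,
    converged = fit$converged == 1L,
    flagged = fit$separated == 1L | fit$converged != 1L | !is.finite(chi2),
    test = "wald")
  # Wald degenerates under (quasi-)separation (Hauck-Donner); flagged fits
  # fall back to the Rao score test, which is finite under the null model
  for (i in which(res$flagged)) {
    st <- score_test_one(C, G[, i], y)
    res[i, `:=`(chi2 = st["chi2"], p = st["p"], test = "score")]
  }
  data.table::setattr(res, "class", c("assoc_result", class(res)))
  res[]
}

# Rao score test for the dosage term: null model = covariates only,
# refit on the variant's complete cases
score_test_one <- function(C, g, y) {
  ok <- which(!is.na(g))
  if (length(ok) < ncol(C) + 3L) return(c(chi2 = NA_real_, p = NA_real_))
  X <- C[ok, , drop = FALSE]; gg <- g[ok]; yy <- y[ok]
  null <- suppressWarnings(glm.fit(X, yy, family = binomial()))
  mu <- null$fitted.values
  w <- pmax(mu * (1 - mu), 1e-10)
  U <- sum(gg * (yy - mu))
  XtWX <- crossprod(X, X * w)
  XtWg <- crossprod(X, gg * w)
  V <- sum(gg^2 * w) - drop(crossprod(XtWg, solve(XtWX, XtWg)))
  if (!is.finite(V) || V <= 0) return(c(chi2 = NA_real_, p = NA_real_))
  chi2 <- U^2 / V
  c(chi2 = chi2,
    p = max(pchisq(chi2, 1L, lower.tail = FALSE), .Machine$double.xmin))
}

#' Max-statistic permutation threshold
#'
#' Permutes the trait labels `n_perm` times (seeded), reruns the logistic
#' scan on each permutation (covariates refit), and records the genome-wide
#' maximum `-log10(p)` over unflagged variants. The threshold is the
#' `ceiling((1 - alpha) * n_perm)`-th order statistic of those maxima (for
#' `n_perm = 1000`, `alpha = 0.01`: the 990th).
#'
#' @inheritParams logistic_scan
#' @param n_perm number of permutations (default 1000; below 100 warns)
#' @param alpha family-wise level (default 0.01)
#' @param seed RNG seed for the permutations
#' @return list(threshold, maxima, n_perm, alpha) — threshold on the
#'   `-log10(p)` scale
#' @export
permutation_threshold <- function(dosages, trait, covariates = NULL,
                                  n_perm = 1000L, alpha = 0.01, seed = 1L) {
  if (n_perm < 100L)
    warning(sprintf("n_perm = %d is low; threshold will be noisy", n_perm),
            call. = FALSE)
  trait <- as.numeric(trait)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- trait
      obs <- which(!is.na(trait))
      yp[obs] <- trait[sample(obs)]
      sc <- logistic_scan(dosages, yp, covariates)
      pv <- sc$p[!is.na(sc$p)]
      if (!length(pv)) return(0)
      max(-log10(pv))
    }, numeric(1))
  })
  k <- ceiling((1 - alpha) * n_perm)
  list(threshold = sort(maxima)[k], maxima = maxima,
       n_perm = n_perm, alpha = alpha)
}

#' Association scan with permutation significance and peak calling
#'
#' @inheritParams permutation_threshold
#' @param min_count,max_gap peak-calling parameters (see [call_peaks()])
#' @return list(assoc, perm, hits, peaks)
#' @export
run_association <- function(dosages, trait, covariates = NULL,
                            n_perm = 1000L, alpha = 0.01, seed = 1L,
                            min_count = 5L, max_gap = 100000L) {
  assoc <- logistic_scan(dosages, trait, covariates)
  perm <- permutation_threshold(dosages, trait, covariates,
                                n_perm = n_perm, alpha = alpha, seed = seed)
  hits <- assoc[!is.na(p) & -log10(p) > perm$threshold]
  # flagged variants are reported among hits but never drive peak calling
  peaks <- call_peaks(hits[flagged == FALSE, .(chrom, pos, p_adj = p)],
                      min_count = min_count, max_gap = max_gap)
  list(assoc = assoc, perm = perm, hits = hits, peaks = peaks)
}
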