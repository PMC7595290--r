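# Population structure: standardized-genotype PCA and BIC-selected k-means.
# PC scores stand in for DAPC's discriminant scores as scan phenotypes: with
# well-separated groups PC1 and LD1 are monotonically related.

#' Standardize a dosage matrix
#'
#' Per variant: missing entries are mean-imputed, the row is centered by
#' `2 * p_hat` and scaled by `sqrt(2 * p_hat * (1 - p_hat))` where `p_hat` is
#' the sample alternate-allele frequency over called genotypes. Zero-variance
#' variants are dropped with a warning.
#'
#' @param dosages variants x individuals matrix in 0/1/2 (NA allowed)
#' @return list(x = standardized matrix, p_hat, kept = row indices kept)
#' @export
standardize_dosages <- function(dosages) {
  called <- rowSums(!is.na(dosages))
  all_missing <- called == 0L
  p_hat <- rowSums(dosages, na.rm = TRUE) / (2 * pmax(called, 1L))
  # zero variance among called genotypes (monomorphic or constant-het rows)
  ex2 <- rowSums(dosages^2, na.rm = TRUE) / pmax(called, 1L)
  v0 <- ex2 - (2 * p_hat)^2
  keep <- !all_missing & v0 > 1e-12
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance/all-missing variants",
                    sum(!keep)), call. = FALSE)
  x <- dosages[keep, , drop = FALSE]
  storage.mode(x) <- "double"
  p <- p_hat[keep]
  mu <- 2 * p
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx)) x[na_idx] <- mu[na_idx[, 1L]]
  x <- (x - mu) / sqrt(2 * p * (1 - p))
  list(x = x, p_hat = p, kept = which(keep))
}

#' PCA of standardized genotypes
#'
#' Top-k eigendecomposition of the individual-by-individual covariance of the
#' standardized matrix. Per-component sign is fixed by forcing the
#' largest-magnitude variant loading positive, so scores are reproducible.
#'
#' @param std output of [standardize_dosages()] (or a bare standardized
#'   matrix, variants x individuals)
#' @param k number of components, `k <= min(n - 1, m)`
#' @return list of class `pca_result`: `scores` (individuals x k),
#'   `eigenvalues` (length k, non-increasing), `loadings` (variants x k),
#'   `total_variance`
#' @export
pca_dosages <- function(std, k) {
  x <- if (is.list(std)) std$x else std
  n <- ncol(x); m <- nrow(x)
  if (k > min(n - 1L, m))
    stopf("k = %d exceeds min(n - 1, m) = %d", k, min(n - 1L, m))
  sv <- svd(t(x), nu = k, nv = k)
  eigenvalues <- sv$d[seq_len(k)]^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  flip <- vapply(seq_len(k), function(j) {
    l <- loadings[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, "*")
  loadings <- sweep(loadings, 2L, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 loadings = loadings,
                 total_variance = sum(x^2) / (n - 1)),
            class = "pca_result")
}

#' Select the number of clusters by BIC and assign labels
#'
#' For each candidate `k` in `1..k_max`, k-means (multiple restarts, seeded)
#' is run on the score matrix and `BIC(k) = n ln(WSS_k / n) + k ln(n)` is
#' recorded; the `k` minimizing BIC is returned with its labels.
#'
#' @param scores individuals x components matrix (e.g. `pca$scores`)
#' @param k_max largest k scanned (`k_max <= n`)
#' @param nstart k-means restarts per k (default 10)
#' @param seed RNG seed for the restarts (default 1)
#' @return list of class `cluster_model`: `k`, `labels`, `centers`, `bic`
#'   (named vector over candidate k)
#' @export
select_k_and_cluster <- function(scores, k_max, nstart = 10L, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max < 1L) stopf("k_max must be >= 1")
  if (n < k_max) stopf("n = %d individuals < k_max = %d", n, k_max)
  with_seed(seed, {
    fits <- vector("list", k_max)
    bic <- numeric(k_max)
    total_ss <- sum(scale(scores, scale = FALSE)^2)
    for (k in seq_len(k_max)) {
      fit <- if (k == 1L) {
        list(cluster = rep(1L, n),
             centers = matrix(colMeans(scores), 1L),
             tot.withinss = total_ss)
      } else if (k == n) {
        # stats::kmeans refuses k = n; the partition is forced anyway
        list(cluster = seq_len(n), centers = scores, tot.withinss = 0)
      } else suppressWarnings(
        kmeans(scores, centers = k, nstart = nstart, iter.max = 50L))
      # WSS = 0 (k = n, duplicated points) must stay finite under the log
      wss <- max(fit$tot.withinss, 1e-12)
      bic[k] <- n * log(wss / n) + k * log(n)
      fits[[k]] <- fit
    }
    k_best <- which.min(bic)
    names(bic) <- paste0("k", seq_len(k_max))
    structure(list(k = k_best, labels = fits[[k_best]]$cluster,
                   centers = fits[[k_best]]$centers, bic = bic),
              class = "cluster_model")
  })
}

#' Full structure analysis from a variant table
#'
#' Convenience wrapper: dosages -> standardization -> PCA -> BIC clustering.
#'
#' @param vt a biallelic [variant_table()]
#' @param n_pc components to extract (default 20)
#' @param k_max candidate cluster range (default 8)
#' @param n_pc_cluster components used for clustering; defaults to
#'   `min(20, n - 1, n_pc)` so the BIC penalty is not swamped by splitting
#'   isotropic noise directions
#' @param seed RNG seed for k-means restarts
#' @return list with `pca`, `clusters`, `scores`
#' @export
run_structure <- function(vt, n_pc = 20L, k_max = 8L,
                          n_pc_cluster = NULL, seed = 1L) {
  d <- to_dosages(vt)
  std <- standardize_dosages(d)
  n <- ncol(std$x)
  n_pc <- min(n_pc, n - 1L, nrow(std$x))
  pca <- pca_dosages(std, n_pc)
  n_pc_cluster <- n_pc_cluster %||% min(20L, n - 1L, n_pc)
  cl <- select_k_and_cluster(pca$scores[, seq_len(n_pc_cluster), drop = FALSE],
                             k_max = min(k_max, n), seed = seed)
  list(pca = pca, clusters = cl, scores = pca$scores)
}
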