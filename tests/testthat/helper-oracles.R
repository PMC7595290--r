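# Independent oracles used across tests. These deliberately avoid the code
# paths they check: lm() instead of the vectorized scan, hand Pearson sums
# instead of cor(), global brute force instead of the windowed prune sweep.

# two-pass OLS via base lm(), one variant at a time
oracle_ols <- function(dosage, score) {
  ok <- !is.na(dosage)
  fit <- lm(score[ok] ~ dosage[ok])
  s <- summary(fit)$coefficients
  c(beta = unname(s[2, 1]), se = unname(s[2, 2]))
}

# Pearson r from explicit sums
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# all maximal chains of positions with consecutive gap <= max_gap (one chrom)
oracle_chains <- function(pos, min_count, max_gap) {
  pos <- sort(pos)
  if (!length(pos)) return(list())
  breaks <- which(diff(pos) > max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(pos))
  out <- list()
  for (i in seq_along(starts)) {
    members <- pos[starts[i]:ends[i]]
    if (length(members) >= min_count)
      out[[length(out) + 1L]] <- c(start = min(members), end = max(members),
                                   n = length(members))
  }
  out
}

# documented prune rule applied globally (no windowed sweep): keeps removing
# the variant with most r2 >= thresh partners within window_bp until every
# variant has < max_linked partners; ties by lower MAF then larger position
oracle_prune <- function(pos, maf, d, window_bp, r2_thresh, max_linked) {
  m <- length(pos)
  r2 <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))^2
  adj <- (r2 >= r2_thresh) & abs(outer(pos, pos, "-")) <= window_bp
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  alive <- rep(TRUE, m)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) < max_linked) break
    cand <- which(deg == max(deg))
    cand <- cand[order(maf[cand], -pos[cand])]
    alive[cand[1]] <- FALSE
  }
  which(alive)
}

# adjusted Rand index between two labelings
adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
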