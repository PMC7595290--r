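# The study's three successive variant filters:
#   1. basic:  biallelic SNPs, FILTER pass, call rate >= 0.9, MAF >= 0.05
#   2. allele balance: drop a variant if ANY heterozygous call has
#      min(AD)/max(AD) < 0.2 (collapsed-paralog artifact heuristic)
#   3. LD prune: <= 2 mutually linked (r2 >= 0.4) variants per 20-kbp window

new_filter_report <- function(n_input, removed, removed_ids) {
  n_rm <- sum(unlist(removed))
  structure(list(n_input = n_input, n_output = n_input - n_rm,
                 removed = removed, removed_ids = removed_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d -> %d variants\n", x$n_input, x$n_output))
  for (nm in names(x$removed))
    if (x$removed[[nm]] > 0) cat(sprintf("  %-14s %d removed\n", nm, x$removed[[nm]]))
  invisible(x)
}

variant_key <- function(sites) paste0(sites$chrom, ":", sites$pos)

#' Basic site filter
#'
#' Retains biallelic SNPs whose FILTER is `PASS` or `.`, with call rate at
#' least `1 - max_missing_frac` and MAF at least `maf_min` (MAF over called
#' genotypes). Order is preserved; removal reasons are tallied in priority
#' order non-biallelic > indel > failed_filter > missingness > maf.
#'
#' @param vt a [variant_table()]
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param max_missing_frac maximum fraction of missing genotypes (default 0.10)
#' @return list(vt = filtered table, report = filter_report)
#' @export
basic_filter <- function(vt, maf_min = 0.05, max_missing_frac = 0.10) {
  s <- vt$sites
  multi <- grepl(",", s$alt, fixed = TRUE)
  snp_alleles <- !multi & s$ref %in% c("A", "C", "G", "T") &
    s$alt %in% c("A", "C", "G", "T")
  indel <- !multi & !snp_alleles
  failed <- !(s$filter %in% c("PASS", "."))
  # site summaries only defined on biallelic records
  ok_allele <- !multi & !indel
  call_rate <- maf <- rep(NA_real_, nrow(s))
  if (any(ok_allele)) {
    ss <- site_summaries(vt_subset(vt, which(ok_allele)))
    call_rate[ok_allele] <- ss$call_rate
    maf[ok_allele] <- ss$maf
  }
  reason <- rep(NA_character_, nrow(s))
  reason[is.na(reason) & multi] <- "non_biallelic"
  reason[is.na(reason) & indel] <- "indel"
  reason[is.na(reason) & failed] <- "failed_filter"
  reason[is.na(reason) & ok_allele & call_rate < 1 - max_missing_frac] <- "missingness"
  reason[is.na(reason) & ok_allele &
           (is.na(maf) | maf < maf_min)] <- "maf"
  keep <- is.na(reason)
  removed <- as.list(table(factor(reason, levels = c("non_biallelic", "indel",
    "failed_filter", "missingness", "maf"))))
  report <- new_filter_report(nrow(s), removed,
                              variant_key(s)[!keep])
  list(vt = vt_subset(vt, which(keep)), report = report)
}

# balance ratio per het call; NA where AD absent/unparseable or AD = (0,0)
het_balance_ratios <- function(vt) {
  cls <- genotype_class(vt)
  het <- cls == "het"
  rho <- matrix(NA_real_, nrow(cls), ncol(cls))
  if (is.null(vt$ad) || !any(het)) return(rho)
  idx <- which(het & !is.na(vt$ad))
  if (!length(idx)) return(rho)
  # for multiallelic hets use the depths of the two called alleles
  parts <- strsplit(vt$ad[idx], ",", fixed = TRUE)
  a1 <- vt$a1[idx]; a2 <- vt$a2[idx]
  rho[idx] <- vapply(seq_along(idx), function(j) {
    counts <- suppressWarnings(as.integer(parts[[j]]))
    if (anyNA(counts)) return(NA_real_)
    i1 <- a1[j] + 1L; i2 <- a2[j] + 1L
    if (max(i1, i2) > length(counts)) return(NA_real_)
    lo <- min(counts[i1], counts[i2]); hi <- max(counts[i1], counts[i2])
    if (hi == 0L) return(NA_real_)  # AD = (0,0): uninformative
    lo / hi
  }, numeric(1))
  rho
}

#' Allele-balance filter
#'
#' For every heterozygous call compute the balance ratio
#' `rho = min(AD) / max(AD)` of the two called alleles. If `rho < min_ratio`
#' for ANY individual, the whole variant is removed. Het calls lacking AD, or
#' with AD = (0, 0), never trigger removal; they are counted in the report.
#'
#' @param vt a [variant_table()] with AD for het calls
#' @param min_ratio removal threshold on the balance ratio (default 0.2)
#' @return list(vt, report); the report also carries `n_uninformative`, the
#'   number of het calls whose AD could not be used
#' @export
allele_balance_filter <- function(vt, min_ratio = 0.2) {
  rho <- het_balance_ratios(vt)
  cls <- genotype_class(vt)
  n_unin <- sum(cls == "het" & is.na(rho))
  fail <- rowSums(rho < min_ratio, na.rm = TRUE) > 0L
  report <- new_filter_report(nrow(vt$sites),
                              list(allele_balance = sum(fail)),
                              variant_key(vt$sites)[fail])
  report$n_uninformative <- n_unin
  list(vt = vt_subset(vt, which(!fail)), report = report)
}

# r2 between dosage rows over pairwise-complete individuals
dosage_r2_matrix <- function(d) {
  suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))^2
}

# Documented pruning rule, applied to one set of variants (positions bp,
# dosage rows): build the graph of pairs with r2 >= r2_thresh whose positions
# are within window_bp; while some variant has >= max_linked high-LD partners,
# remove the variant with the highest degree, ties broken by lower MAF then
# larger position. Returns indices (into the input) to drop.
prune_rule <- function(pos, maf, r2, window_bp, r2_thresh, max_linked) {
  m <- length(pos)
  adj <- (r2 >= r2_thresh) & abs(outer(pos, pos, "-")) <= window_bp
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  alive <- rep(TRUE, m)
  drop <- integer()
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) < max_linked) break
    cand <- which(deg == max(deg))
    cand <- cand[order(maf[cand], -pos[cand])]
    v <- cand[1]
    alive[v] <- FALSE
    drop <- c(drop, v)
  }
  drop
}

#' LD pruning
#'
#' Emulates windowed LD thinning: within any `window_bp` span at most
#' `max_linked` variants remain that are pairwise in LD at `r2 >= r2_thresh`.
#' The sweep walks each chromosome left to right; within the active window the
#' variant with the most high-LD partners is removed first, ties broken by
#' lower MAF then larger position, until no variant has `max_linked` or more
#' partners. This is a deterministic emulation of the cited plugin
#' (`+prune -w 20kb -l 0.4 -n 2`), not a bit-exact clone.
#'
#' @param vt a biallelic [variant_table()]
#' @param window_bp window size in base pairs (default 20000)
#' @param r2_thresh genotype r2 threshold (default 0.4)
#' @param max_linked maximum mutually linked variants kept per window
#'   (default 2)
#' @return list(vt, report)
#' @export
ld_prune <- function(vt, window_bp = 20000L, r2_thresh = 0.4,
                     max_linked = 2L) {
  d <- to_dosages(vt)
  ss <- site_summaries(vt)
  m <- nrow(d)
  dropped <- rep(FALSE, m)
  for (chr in unique(vt$sites$chrom)) {
    rows <- which(vt$sites$chrom == chr)
    if (length(rows) < 2L) next
    pos <- vt$sites$pos[rows]
    # process overlapping windows anchored at each variant
    i <- 1L
    while (i <= length(rows)) {
      win <- which(pos >= pos[i] & pos <= pos[i] + window_bp & !dropped[rows])
      if (length(win) >= 2L) {
        sub <- rows[win]
        r2 <- dosage_r2_matrix(d[sub, , drop = FALSE])
        dr <- prune_rule(pos[win], ss$maf[sub], r2, window_bp, r2_thresh,
                         max_linked)
        dropped[sub[dr]] <- TRUE
      }
      i <- i + 1L
    }
  }
  report <- new_filter_report(m, list(ld_prune = sum(dropped)),
                              variant_key(vt$sites)[dropped])
  list(vt = vt_subset(vt, which(!dropped)), report = report)
}

#' Run the three filters as the study's pipeline
#'
#' basic -> allele balance -> LD prune, with a chained report whose counts
#' conserve (`n_output` of each stage equals `n_input` of the next).
#'
#' @param vt a [variant_table()]
#' @inheritParams basic_filter
#' @inheritParams allele_balance_filter
#' @inheritParams ld_prune
#' @param stages character subset of c("basic", "balance", "prune")
#' @return list(vt, reports = named list of filter_report)
#' @export
filter_pipeline <- function(vt, maf_min = 0.05, max_missing_frac = 0.10,
                            min_ratio = 0.2, window_bp = 20000L,
                            r2_thresh = 0.4, max_linked = 2L,
                            stages = c("basic", "balance", "prune")) {
  reports <- list()
  if ("basic" %in% stages) {
    st <- basic_filter(vt, maf_min, max_missing_frac)
    vt <- st$vt; reports$basic <- st$report
  }
  if ("balance" %in% stages) {
    st <- allele_balance_filter(vt, min_ratio)
    vt <- st$vt; reports$balance <- st$report
  }
  if ("prune" %in% stages) {
    st <- ld_prune(vt, window_bp, r2_thresh, max_linked)
    vt <- st$vt; reports$prune <- st$report
  }
  list(vt = vt, reports = reports)
}
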