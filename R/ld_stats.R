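# Genotype r2 linkage-disequilibrium statistics: exact within-chromosome
# pair listing, LD-block extraction around a lead variant, and the
# long-range-LD 1-Mbp window track.

#' Genotype r-squared between two dosage vectors
#'
#' Squared Pearson correlation of dosages over individuals called in both
#' vectors (complete-case; no imputation). Undefined (NA) when fewer than 3
#' co-called individuals or either vector is constant on the co-called set.
#'
#' @param x,y dosage vectors in 0/1/2 (NA allowed)
#' @return r2 in `[0, 1]`, or NA
#' @export
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' All within-chromosome LD pairs above a threshold
#'
#' Exact all-pairs computation (no windowing); `O(m^2)` is accepted at desk
#' scale.
#'
#' @param vt a biallelic [variant_table()]
#' @param chrom chromosome name
#' @param min_r2 minimum r2 to report (default 0.5)
#' @return data.table: pos_a, pos_b (pos_a < pos_b), distance, r2
#' @export
chromosome_pairs <- function(vt, chrom, min_r2 = 0.5) {
  rows <- which(vt$sites$chrom == chrom)
  if (!length(rows)) stopf("unknown chromosome '%s'", chrom)
  empty <- data.table::data.table(pos_a = integer(), pos_b = integer(),
                                  distance = integer(), r2 = numeric())
  if (length(rows) < 2L) return(empty)
  d <- to_dosages(vt_subset(vt, rows))
  pos <- vt$sites$pos[rows]
  r2 <- dosage_r2_matrix(d)
  idx <- which(upper.tri(r2) & !is.na(r2) & r2 >= min_r2, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.table::data.table(
    pos_a = pos[idx[, 1]], pos_b = pos[idx[, 2]],
    distance = abs(pos[idx[, 2]] - pos[idx[, 1]]),
    r2 = r2[idx])
  out[pos_a > pos_b, c("pos_a", "pos_b") := .(pos_b, pos_a)]
  data.table::setorder(out, pos_a, pos_b)
  out[]
}

#' LD block around a lead variant
#'
#' All same-chromosome variants whose genotype r2 with the lead is at least
#' `min_r2` (the lead itself included); used to visualize the genomic extent
#' of LD around the most significant scan variant.
#'
#' @param vt a biallelic [variant_table()]
#' @param chrom,lead_pos coordinates of the lead variant
#' @param min_r2 membership threshold (default 0.3)
#' @return list(lead_pos, members = data.table(pos, r2), start, end, span)
#' @export
block_around_lead <- function(vt, chrom, lead_pos, min_r2 = 0.3) {
  rows <- which(vt$sites$chrom == chrom)
  if (!length(rows)) stopf("unknown chromosome '%s'", chrom)
  pos <- vt$sites$pos[rows]
  li <- which(pos == lead_pos)
  if (length(li) != 1L)
    stopf("lead variant %s:%d not found", chrom, lead_pos)
  d <- to_dosages(vt_subset(vt, rows))
  lead_g <- d[li, ]
  if (length(unique(lead_g[!is.na(lead_g)])) < 2L)
    stopf("lead variant %s:%d is monomorphic", chrom, lead_pos)
  r2 <- vapply(seq_len(nrow(d)), function(i) genotype_r2(lead_g, d[i, ]),
               numeric(1))
  r2[li] <- 1
  member <- which(!is.na(r2) & r2 >= min_r2)
  members <- data.table::data.table(pos = pos[member], r2 = r2[member])
  data.table::setorder(members, pos)
  list(lead_pos = lead_pos, members = members,
       start = min(members$pos), end = max(members$pos),
       span = max(members$pos) - min(members$pos))
}

#' Long-range LD window track
#'
#' Tiles a chromosome in fixed windows and, per window, counts the distinct
#' variants located there that have at least one LD partner (`r2 >= 0.5`
#' pairs, precomputed) at distance `>= min_dist`. Emits `log10(count + 1)`
#' alongside the raw count (the +1 offset handles empty windows).
#'
#' @param pairs data.table from [chromosome_pairs()] (r2 >= 0.5)
#' @param chrom chromosome name for the output
#' @param chrom_length chromosome length in bp
#' @param window window size in bp (default 1e6)
#' @param min_dist minimum partner distance in bp (default 1e5)
#' @return data.table: chrom, start, end (1-based inclusive tiling), count,
#'   log_count
#' @export
longrange_track <- function(pairs, chrom, chrom_length, window = 1000000L,
                            min_dist = 100000L) {
  n_win <- ceiling(chrom_length / window)
  starts <- as.integer((seq_len(n_win) - 1L) * window + 1L)
  ends <- as.integer(pmin(seq_len(n_win) * window, chrom_length))
  counts <- integer(n_win)
  far <- pairs[distance >= min_dist]
  if (nrow(far)) {
    vars <- unique(c(far$pos_a, far$pos_b))
    w <- pmin((vars - 1L) %/% window + 1L, n_win)
    tab <- table(w)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  data.table::data.table(chrom = chrom, start = starts, end = ends,
                         count = counts, log_count = log10(counts + 1))
}

#' Write a window track as BED-like TSV
#'
#' Coordinates are converted to 0-based half-open ONLY in this export
#' (columns chrom, start0, end, count, log_count).
#'
#' @param track output of [longrange_track()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_track_bed <- function(track, path) {
  out <- data.table::data.table(chrom = track$chrom, start0 = track$start - 1L,
                                end = track$end, count = track$count,
                                log_count = track$log_count)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
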