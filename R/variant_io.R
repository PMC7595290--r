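# VCF reading/writing and genotype -> dosage conversion.
#
# A variant_table keeps, per site, the two called allele indices (a1, a2;
# NA = missing), the raw AD string and DP, so that read -> write -> read is a
# fixed point (phase separators are normalized to "/" on the first write).

#' Construct a variant table
#'
#' Container for parsed VCF records: site metadata plus per-sample diploid
#' allele indices and (optionally) allelic depths and total depth.
#'
#' @param sites data.table with columns chrom, pos, id, ref, alt, qual, filter,
#'   info (alt is the comma-joined ALT field; pos 1-based)
#' @param samples character vector of sample ids (column order of the call
#'   matrices)
#' @param a1,a2 integer matrices (variants x samples) of allele indices
#'   (0 = REF, 1 = first ALT, ...), NA for missing calls
#' @param ad optional character matrix of raw AD strings (NA where absent)
#' @param dp optional integer matrix of per-call depth
#' @param meta character vector of "##" header lines (a minimal header is
#'   synthesized if omitted)
#' @return an object of class `variant_table`
#' @export
variant_table <- function(sites, samples, a1, a2, ad = NULL, dp = NULL,
                          meta = NULL) {
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$id)) sites[, id := "."]
  if (is.null(sites$qual)) sites[, qual := "."]
  if (is.null(sites$filter)) sites[, filter := "PASS"]
  if (is.null(sites$info)) sites[, info := "."]
  m <- nrow(sites); n <- length(samples)
  stopifnot(identical(dim(a1), c(m, n)), identical(dim(a2), c(m, n)))
  if (any(sites$pos < 1L)) stopf("positions must be 1-based (>= 1)")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord]
    a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
    if (!is.null(ad)) ad <- ad[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  }
  structure(list(sites = sites, samples = samples, a1 = a1, a2 = a2,
                 ad = ad, dp = dp, meta = meta),
            class = "variant_table")
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples (%s AD, %s DP)\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$ad)) "no" else "with",
              if (is.null(x$dp)) "no" else "with"))
  invisible(x)
}

#' Subset a variant table by variant index
#' @param vt a `variant_table`
#' @param i integer or logical index over variants
#' @return the subsetted `variant_table`
#' @export
vt_subset <- function(vt, i) {
  variant_table(vt$sites[i], vt$samples,
                vt$a1[i, , drop = FALSE], vt$a2[i, , drop = FALSE],
                if (!is.null(vt$ad)) vt$ad[i, , drop = FALSE],
                if (!is.null(vt$dp)) vt$dp[i, , drop = FALSE],
                vt$meta)
}

#' Read a VCF file
#'
#' Parses VCF v4.x with diploid GT (AD and DP optional; other FORMAT keys are
#' dropped). `./.` and `.` become missing calls; the FILTER column is retained
#' verbatim. Gzip-compressed files are read transparently.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file
#' @return a [variant_table()]
#' @export
read_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- grep("^##", lines)
  chrom_line <- grep("^#CHROM", lines)
  if (length(chrom_line) != 1L)
    stopf("malformed VCF header in %s: no #CHROM line", path)
  meta <- lines[hdr]
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stopf("VCF %s has no sample columns (line %d)", path, chrom_line)
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(chrom_line)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    m0 <- matrix(NA_integer_, 0, length(samples))
    return(variant_table(
      data.table::data.table(chrom = character(), pos = integer(),
                             id = character(), ref = character(),
                             alt = character(), qual = character(),
                             filter = character(), info = character()),
      samples, m0, m0, meta = meta))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  bad <- which(nf != length(cols))
  if (length(bad))
    stopf("malformed VCF record at line %d: %d fields, expected %d",
          chrom_line + bad[1], nf[bad[1]], length(cols))
  rec <- matrix(unlist(f), nrow = length(body), byrow = TRUE)
  sites <- data.table::data.table(
    chrom = rec[, 1], pos = as.integer(rec[, 2]), id = rec[, 3],
    ref = rec[, 4], alt = rec[, 5], qual = rec[, 6], filter = rec[, 7],
    info = rec[, 8])
  fmt <- rec[, 9]
  calls <- rec[, -(1:9), drop = FALSE]
  m <- nrow(calls); n <- ncol(calls)
  a1 <- matrix(NA_integer_, m, n); a2 <- matrix(NA_integer_, m, n)
  ad <- matrix(NA_character_, m, n); dp <- matrix(NA_integer_, m, n)
  any_ad <- FALSE; any_dp <- FALSE
  # records sharing a FORMAT string are parsed in one vectorized pass
  for (fstr in unique(fmt)) {
    rows <- which(fmt == fstr)
    keys <- strsplit(fstr, ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", keys); ad_i <- match("AD", keys); dp_i <- match("DP", keys)
    if (is.na(gt_i))
      stopf("FORMAT without GT at line %d", chrom_line + rows[1])
    v <- as.vector(calls[rows, , drop = FALSE])
    parts <- data.table::tstrsplit(v, ":", fixed = TRUE)
    gt <- parts[[gt_i]]
    al <- data.table::tstrsplit(gt, "[/|]")
    if (length(al) > 2L && any(!is.na(al[[3]]) & nzchar(al[[3]])))
      stopf("non-diploid GT near line %d", chrom_line + rows[1])
    g1 <- suppressWarnings(as.integer(al[[1]]))
    g2 <- if (length(al) >= 2L) suppressWarnings(as.integer(al[[2]]))
          else rep(NA_integer_, length(g1))
    haploid <- !is.na(g1) & is.na(g2) & gt != "." & !grepl("[/|]", gt)
    if (any(haploid)) {
      i <- which(haploid)[1]
      stopf("non-diploid GT '%s' at line %d", gt[i],
            chrom_line + rows[(i - 1L) %% length(rows) + 1L])
    }
    miss <- is.na(g1) | is.na(g2)
    g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
    a1[rows, ] <- matrix(g1, length(rows)); a2[rows, ] <- matrix(g2, length(rows))
    if (!is.na(ad_i) && length(parts) >= ad_i) {
      adv <- parts[[ad_i]]
      adv[!is.na(adv) & adv == "."] <- NA_character_
      ad[rows, ] <- matrix(adv, length(rows)); any_ad <- TRUE
    }
    if (!is.na(dp_i) && length(parts) >= dp_i) {
      dpv <- suppressWarnings(as.integer(parts[[dp_i]]))
      dp[rows, ] <- matrix(dpv, length(rows)); any_dp <- TRUE
    }
  }
  variant_table(sites, samples, a1, a2,
                ad = if (any_ad) ad else NULL,
                dp = if (any_dp) dp else NULL, meta = meta)
}

#' Write a variant table as VCF v4.2
#'
#' Genotypes are written unphased (`/`). Records carry `GT:AD:DP`, `GT:AD`,
#' `GT:DP` or `GT` depending on which fields the table holds.
#'
#' @param vt a [variant_table()]
#' @param path output path (`.gz` suffix writes gzip)
#' @return `path`, invisibly
#' @export
write_vcf <- function(vt, path) {
  meta <- vt$meta %||% c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  m <- nrow(vt$sites); n <- length(vt$samples)
  gt <- matrix(paste(ifelse(is.na(vt$a1), ".", vt$a1),
                     ifelse(is.na(vt$a2), ".", vt$a2), sep = "/"), m, n)
  gt[is.na(vt$a1) & is.na(vt$a2)] <- "./."
  has_ad <- !is.null(vt$ad); has_dp <- !is.null(vt$dp)
  fmt <- paste(c("GT", if (has_ad) "AD", if (has_dp) "DP"), collapse = ":")
  call_str <- gt
  if (has_ad) call_str <- matrix(paste(call_str, ifelse(is.na(vt$ad), ".", vt$ad),
                                       sep = ":"), m, n)
  if (has_dp) call_str <- matrix(paste(call_str, ifelse(is.na(vt$dp), ".", vt$dp),
                                       sep = ":"), m, n)
  body <- if (m > 0L) {
    left <- do.call(paste, c(vt$sites[, .(chrom, pos, id, ref, alt, qual,
                                          filter, info)],
                             list(fmt, sep = "\t")))
    paste(left, apply(call_str, 1L, paste, collapse = "\t"), sep = "\t")
  } else character()
  out <- c(meta,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"),
           body)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Classify calls of a variant table
#'
#' @param vt a [variant_table()]
#' @return character matrix with entries `hom_ref`, `het`, `hom_alt`, `missing`
#' @export
genotype_class <- function(vt) {
  cls <- matrix("missing", nrow(vt$sites), length(vt$samples))
  ok <- !is.na(vt$a1) & !is.na(vt$a2)
  cls[ok & vt$a1 == 0L & vt$a2 == 0L] <- "hom_ref"
  cls[ok & vt$a1 != vt$a2] <- "het"
  cls[ok & vt$a1 == vt$a2 & vt$a1 > 0L] <- "hom_alt"
  cls
}

is_biallelic_snp <- function(sites) {
  !grepl(",", sites$alt, fixed = TRUE) &
    nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$alt %in% c("A", "C", "G", "T")
}

#' Convert a biallelic variant table to a dosage matrix
#'
#' Alternate-allele dosage per call: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2,
#' missing -> NA. Missing is preserved, never imputed here.
#'
#' @param vt a [variant_table()] of biallelic records
#' @return integer matrix (variants x samples) with attributes `chrom`, `pos`
#' @export
to_dosages <- function(vt) {
  multi <- grepl(",", vt$sites$alt, fixed = TRUE)
  if (any(multi))
    stopf("to_dosages: multiallelic record at %s:%d (filter first)",
          vt$sites$chrom[which(multi)[1]], vt$sites$pos[which(multi)[1]])
  d <- vt$a1 + vt$a2
  mode(d) <- "integer"
  structure(d, chrom = vt$sites$chrom, pos = vt$sites$pos,
            dimnames = list(NULL, vt$samples))
}

#' Per-variant minor allele frequency and call rate
#'
#' MAF is computed over called genotypes only (`min(f_alt, 1 - f_alt)`); sites
#' with zero called genotypes get `call_rate = 0` and `NA` MAF, flagged in the
#' `undefined` column.
#'
#' @param vt a biallelic [variant_table()]
#' @return data.table with chrom, pos, call_rate, maf, undefined
#' @export
site_summaries <- function(vt) {
  d <- to_dosages(vt)
  n <- ncol(d)
  called <- rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  f_alt <- ifelse(called > 0L, alt / (2 * called), NA_real_)
  data.table::data.table(
    chrom = vt$sites$chrom, pos = vt$sites$pos,
    call_rate = called / n,
    maf = pmin(f_alt, 1 - f_alt),
    undefined = called == 0L)
}

#' Read a trait/covariate table
#'
#' Tab-separated, header required, first column `sample_id`; remaining columns
#' numeric or binary. Rows are reordered to match `samples` when given.
#'
#' @param path TSV path
#' @param samples optional sample order to enforce
#' @return data.table
#' @export
read_trait_table <- function(path, samples = NULL) {
  tt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"sample_id" %in% names(tt))
    stopf("trait table %s lacks a sample_id column", path)
  if (!is.null(samples)) {
    idx <- match(samples, tt$sample_id)
    if (anyNA(idx))
      stopf("trait table %s missing samples: %s", path,
            paste(head(samples[is.na(idx)], 3), collapse = ", "))
    tt <- tt[idx]
  }
  tt
}
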