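# End-to-end pipeline: simulate (or load a VCF) -> filter -> structure ->
# divergence scan -> association -> LD stats -> diversity, driven by one JSON
# config with a single seed. All tabular outputs are TSV with headers.

#' Default pipeline configuration
#'
#' Every threshold defaults to the study's value (MAF 0.05, 10% missingness,
#' balance ratio 0.2, LD prune 20 kbp / r2 0.4 / keep 2, alpha 0.01, 5
#' significant variants within 100 kbp, permutations 1000, LD pairs r2 0.5,
#' LD block r2 0.3, genome length 1,927,125,257 bp). The bundled demo
#' simulation is small enough for a laptop smoke run.
#'
#' @param seed global integer seed
#' @param out_dir output directory
#' @return nested config list
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("nerkascan_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      pop_sizes = c(30L, 30L, 30L), fst = 0.1, n_loci = 3000L,
      chrom_lengths = list(chr1 = 40000000L, chr2 = 30000000L),
      mean_depth = 30, missing_rate = 0.02,
      haploblock = list(chrom = "chr1", n_loci = 10L,
                        pop_freqs = c(0.95, 0.05, 0.05)),
      n_artifacts = 10L, sex_marker_negative_pop = 3L),
    filters = list(maf_min = 0.05, max_missing_frac = 0.10, min_ratio = 0.2,
                   window_bp = 20000L, r2_thresh = 0.4, max_linked = 2L,
                   stages = c("basic", "balance", "prune")),
    structure = list(n_pc = 20L, k_max = 6L),
    scan = list(alpha = 0.01, min_count = 5L, max_gap = 100000L),
    assoc = list(trait = "sdY_present", n_perm = 200L, alpha = 0.01,
                 covariate_pcs = 2L),
    ld = list(min_r2_pairs = 0.5, min_r2_block = 0.3,
              window = 1000000L, min_dist = 100000L),
    diversity = list(genome_length = 1927125257))
}

# choose a haploblock span covering n consecutive drawn loci on a chromosome
pick_block_span <- function(design, chrom, n_block) {
  loci <- with_seed(design$seed, locus_positions(design))
  rows <- which(loci$chrom == chrom)
  if (length(rows) < n_block + 2L)
    stopf("chromosome %s has too few loci for a %d-locus block", chrom, n_block)
  a <- rows[floor(length(rows) / 2)]
  c(loci$pos[a], loci$pos[a + n_block - 1L])
}

build_planted <- function(design, cfg_sim) {
  planted <- list()
  hb <- cfg_sim$haploblock
  if (!is.null(hb)) {
    span <- pick_block_span(design, hb$chrom, hb$n_loci)
    planted <- c(planted, list(planted_haploblock(hb$chrom, span[1], span[2],
                                                  unlist(hb$pop_freqs))))
  }
  if ((cfg_sim$n_artifacts %||% 0L) > 0L) {
    loci <- with_seed(design$seed, locus_positions(design))
    idx <- with_seed(design$seed + 9L,
                     sort(sample.int(nrow(loci), cfg_sim$n_artifacts)))
    planted <- c(planted, lapply(idx, function(i)
      planted_artifact(loci$chrom[i], loci$pos[i])))
  }
  if (!is.null(cfg_sim$sex_marker_negative_pop))
    planted <- c(planted,
                 list(planted_sex_marker(cfg_sim$sex_marker_negative_pop)))
  planted
}

log_stage <- function(log, stage, n_in, n_out, t0, seed) {
  rbind(log, data.table::data.table(
    stage = stage, n_in = n_in, n_out = n_out,
    seconds = round(as.numeric(Sys.time()) - t0, 3), seed = seed))
}

#' Run the full analysis pipeline
#'
#' Stages are executed in the study's order; each stage writes its TSV/VCF
#' artifacts into `config$out_dir` together with the verbatim serialized
#' config and a machine-readable run log (stage, input/output counts, wall
#' time, seed). A stage failure aborts with the stage name.
#'
#' @param config nested list as produced by [default_config()], or a path to
#'   a JSON file with the same structure
#' @return the output directory, invisibly; the run log is written to
#'   `run_log.tsv`
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  seed <- as.integer(config$seed)
  log <- data.table::data.table(stage = character(), n_in = integer(),
                                n_out = integer(), seconds = numeric(),
                                seed = integer())
  run_stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    list(res = res, t0 = t0)
  }

  # -- simulate ---------------------------------------------------------------
  st <- run_stage("simulate", {
    cs <- config$simulate
    design <- cohort_design(cs$pop_sizes, cs$fst, cs$n_loci,
                            unlist(cs$chrom_lengths), cs$mean_depth,
                            cs$missing_rate, seed = seed)
    cohort <- simulate_cohort(design, build_planted(design, cs))
    write_cohort(cohort, file.path(out, "cohort"))
    cohort
  })
  cohort <- st$res
  log <- log_stage(log, "simulate", 0L, nrow(cohort$vt$sites), st$t0, seed)

  # -- filters ----------------------------------------------------------------
  st <- run_stage("filter", {
    cf <- config$filters
    filter_pipeline(cohort$vt, cf$maf_min, cf$max_missing_frac, cf$min_ratio,
                    cf$window_bp, cf$r2_thresh, cf$max_linked,
                    stages = cf$stages)
  })
  filt <- st$res
  write_vcf(filt$vt, file.path(out, "filtered.vcf"))
  rep_dt <- data.table::rbindlist(lapply(names(filt$reports), function(nm) {
    r <- filt$reports[[nm]]
    data.table::data.table(stage = nm, n_in = r$n_input, n_out = r$n_output)
  }))
  data.table::fwrite(rep_dt, file.path(out, "filter_report.tsv"), sep = "\t")
  log <- log_stage(log, "filter", nrow(cohort$vt$sites), nrow(filt$vt$sites),
                   st$t0, seed)

  # -- structure --------------------------------------------------------------
  st <- run_stage("structure", {
    run_structure(filt$vt, n_pc = config$structure$n_pc,
                  k_max = config$structure$k_max, seed = seed)
  })
  struct <- st$res
  scores_dt <- data.table::data.table(sample_id = filt$vt$samples,
                                      struct$scores,
                                      cluster = struct$clusters$labels)
  data.table::fwrite(scores_dt, file.path(out, "scores.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    k = seq_along(struct$clusters$bic), bic = struct$clusters$bic),
    file.path(out, "bic.tsv"), sep = "\t")
  log <- log_stage(log, "structure", nrow(filt$vt$sites),
                   struct$clusters$k, st$t0, seed)

  # -- divergence scan (on balance-filtered, not LD-pruned, variants) ---------
  st <- run_stage("scan", {
    pre <- filter_pipeline(cohort$vt, config$filters$maf_min,
                           config$filters$max_missing_frac,
                           config$filters$min_ratio,
                           stages = intersect(config$filters$stages,
                                              c("basic", "balance")))
    d <- to_dosages(pre$vt)
    run_divergence_scan(d, struct$scores[, 1L],
                        alpha = config$scan$alpha,
                        min_count = config$scan$min_count,
                        max_gap = config$scan$max_gap)
  })
  scan <- st$res
  data.table::fwrite(scan$scan[, .(chrom, pos, beta, se, chi2, p_raw, p_adj,
                                   significant)],
                     file.path(out, "scan.tsv"), sep = "\t")
  data.table::fwrite(scan$peaks, file.path(out, "peaks.tsv"), sep = "\t")
  log <- log_stage(log, "scan", nrow(scan$scan), nrow(scan$peaks), st$t0, seed)

  # -- association ------------------------------------------------------------
  st <- run_stage("assoc", {
    ca <- config$assoc
    trait <- cohort$sample_sheet[[ca$trait]]
    npc <- min(ca$covariate_pcs %||% 2L, ncol(struct$scores))
    d <- to_dosages(filt$vt)
    run_association(d, trait,
                    covariates = struct$scores[, seq_len(npc), drop = FALSE],
                    n_perm = ca$n_perm, alpha = ca$alpha, seed = seed)
  })
  assoc <- st$res
  data.table::fwrite(assoc$assoc, file.path(out, "assoc.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    threshold = assoc$perm$threshold, n_perm = assoc$perm$n_perm,
    alpha = assoc$perm$alpha), file.path(out, "assoc_threshold.tsv"),
    sep = "\t")
  log <- log_stage(log, "assoc", nrow(assoc$assoc), nrow(assoc$hits),
                   st$t0, seed)

  # -- LD ---------------------------------------------------------------------
  st <- run_stage("ld", {
    cl <- config$ld
    chroms <- unique(filt$vt$sites$chrom)
    pairs <- data.table::rbindlist(lapply(chroms, function(ch)
      data.table::data.table(chrom = ch,
                             chromosome_pairs(filt$vt, ch,
                                              min_r2 = cl$min_r2_pairs))))
    lens <- unlist(config$simulate$chrom_lengths)
    track <- data.table::rbindlist(lapply(chroms, function(ch)
      longrange_track(pairs[chrom == ch], ch, lens[[ch]],
                      window = cl$window, min_dist = cl$min_dist)))
    list(pairs = pairs, track = track)
  })
  data.table::fwrite(st$res$pairs, file.path(out, "ld_pairs.tsv"), sep = "\t")
  write_track_bed(st$res$track, file.path(out, "ld_track.tsv"))
  log <- log_stage(log, "ld", nrow(filt$vt$sites), nrow(st$res$pairs),
                   st$t0, seed)

  # -- diversity --------------------------------------------------------------
  st <- run_stage("diversity", {
    hs <- het_stats(cohort$vt, config$diversity$genome_length)
    segs <- roh_scan(filt$vt)
    list(het = hs, roh = segs,
         totals = total_roh(segs, samples = cohort$vt$samples))
  })
  data.table::fwrite(st$res$het, file.path(out, "diversity_het.tsv"),
                     sep = "\t")
  data.table::fwrite(st$res$roh, file.path(out, "roh.tsv"), sep = "\t")
  data.table::fwrite(st$res$totals, file.path(out, "roh_totals.tsv"),
                     sep = "\t")
  log <- log_stage(log, "diversity", length(cohort$vt$samples),
                   nrow(st$res$roh), st$t0, seed)

  data.table::fwrite(log, file.path(out, "run_log.tsv"), sep = "\t")
  invisible(out)
}
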