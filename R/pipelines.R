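#' Plant a sweep layout over a fraction of the gene grid
#'
#' Chooses a fraction of the configuration's genes (positions are known
#' from the deterministic grid before any simulation) and marks each
#' chosen gene's span, extended by `flank` bp, as a sweep region with
#' the given diversity reduction and SFS skew. The default fraction
#' matches the scan's 5% detection tail: a recovery experiment sized to
#' the band the caller reports.
#'
#' @param cfg a [sim_config()].
#' @param gene_fraction fraction of genes placed under sweeps.
#' @param reduction site-density multiplier inside sweeps.
#' @param skew SFS skew exponent inside sweeps.
#' @param flank bp of hitchhiking flank added on each side of a swept
#'   gene; the 2 kb default makes the diversity reduction cover every
#'   window the gene-aggregation step sees (sweeps extend well beyond
#'   the selected locus itself).
#' @return the configuration with `sweep_regions` set.
#' @export
sweep_recovery_config <- function(cfg, gene_fraction = 0.05,
                                  reduction = 0.2, skew = 2,
                                  flank = 2000L) {
  grid <- gene_grid(cfg)
  n_pick <- max(1L, round(gene_fraction * nrow(grid)))
  set.seed(op_seed(cfg$seed, 6L))
  pick <- sort(sample.int(nrow(grid), n_pick))
  sl <- scaffold_lengths(cfg)
  cfg$sweep_regions <- data.frame(
    scaffold = grid$scaffold[pick],
    start = pmax(0L, grid$start[pick] - flank),
    end = pmin(as.integer(sl[grid$scaffold[pick]]),
               grid$end[pick] + flank),
    diversity_reduction = reduction, sfs_skew = skew,
    stringsAsFactors = FALSE)
  validate_sim_config(cfg)
  cfg
}

#' Run the window -> gene -> joint-percentile selection scan
#'
#' @param snps a [snp_set()].
#' @param genes gene model data.frame.
#' @param genome DNAStringSet or named scaffold lengths.
#' @param window window size in bp.
#' @param coverage optional coverage track for the corrected pi
#'   denominator.
#' @param tail selection tail.
#' @return the gene-score data.frame of [joint_percentile_scan()].
#' @export
run_sweep_scan <- function(snps, genes, genome, window = 1000L,
                           coverage = NULL, tail = 0.05) {
  win <- windowed_diversity(snps, genome, window = window,
                            coverage = coverage)
  map <- suppressWarnings(intersect_genes_windows(genes, win))
  stats <- suppressWarnings(aggregate_gene_stats(map, win))
  joint_percentile_scan(stats, tail = tail)
}

#' End-to-end sweep-recovery experiment
#'
#' Simulates a cohort with planted sweeps, runs the filter cascade and
#' the joint-percentile scan, and scores the call against the truth
#' table.
#'
#' @param seed simulation seed.
#' @param gene_fraction,reduction,skew sweep layout (see
#'   [sweep_recovery_config()]).
#' @param cfg base configuration (defaults to `sim_config(seed = seed)`).
#' @param filter apply the stringent filter preset before scanning. Off
#'   by default: the MAF >= 0.05 step removes exactly the rare variants
#'   that carry the sweep signature, so the recovery experiment isolates
#'   the scan; the cascade is exercised by its own tests and in the
#'   analysis workflow.
#' @param tail selection tail.
#' @return list(sensitivity, precision, n_selected, n_truth, scores,
#'   truth).
#' @export
sweep_recovery_run <- function(seed, gene_fraction = 0.05,
                               reduction = 0.2, skew = 2, cfg = NULL,
                               filter = FALSE, tail = 0.05) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  cfg <- sweep_recovery_config(cfg, gene_fraction, reduction, skew)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(cfg, genome)
  sim <- simulate_variants(cfg, genome, genes)
  coverage <- simulate_coverage(cfg, genome)
  snps <- sim$snps
  if (filter) {
    fc <- filter_preset("round2_final", haploid_sample = snps$haploid)
    snps <- run_filter_cascade(snps, fc)$snps
  }
  scores <- run_sweep_scan(snps, genes, genome, coverage = coverage,
                           tail = tail)
  sel <- scores$gene_id[scores$selected]
  truth <- sim$truth$sweep_gene_ids
  tp <- length(intersect(sel, truth))
  list(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       precision = if (length(sel)) tp / length(sel) else NA_real_,
       n_selected = length(sel), n_truth = length(truth),
       scores = scores, truth = truth)
}

#' Neutral calibration of the generator and the estimators
#'
#' Simulates a fully neutral cohort and reports the windowed diversity
#' summaries (mean corrected pi, mean Tajima's D over defined windows),
#' the singleton fraction of the true SFS against its 1/i expectation,
#' and the mean off-diagonal Ajk relatedness of the diploid cohort.
#'
#' @param seed simulation seed.
#' @param cfg configuration (defaults to `sim_config(seed = seed)`).
#' @return list of summaries.
#' @export
neutral_calibration_run <- function(seed, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  cfg$sweep_regions <- NULL
  genome <- simulate_genome(cfg)
  sim <- simulate_variants(cfg, genome)
  coverage <- simulate_coverage(cfg, genome)
  win <- windowed_diversity(sim$snps, genome, window = 1000L,
                            coverage = coverage)
  tf <- sim$truth$site_freq
  C <- tf$n_chrom[1]
  exp_singleton <- 1 / sum(1 / seq_len(C - 1))
  cohort <- setdiff(sim$snps$samples, sim$snps$haploid)
  ajk <- relatedness_ajk(sim$snps$gt[, cohort, drop = FALSE])
  off <- ajk$ajk[lower.tri(ajk$ajk)]
  list(n_windows = sum(!is.na(win$tajimas_d)),
       mean_pi = mean(win$pi_corrected, na.rm = TRUE),
       mean_d = mean(win$tajimas_d, na.rm = TRUE),
       singleton_fraction = mean(tf$derived_count == 1),
       expected_singleton_fraction = exp_singleton,
       mean_offdiag_ajk = mean(off),
       n_sites_ajk = ajk$n_sites_used,
       windows = win)
}

#' End-to-end motif planted-site recovery experiment
#'
#' Simulates a genome and gene models, plants strong sites of the first
#' motif in a subset of promoters, runs the motif-scoring pipeline, and
#' tests (a) whether the planted genes are captured by the planted
#' motif's conservative 1Kup target set and (b) whether an enrichment
#' run with the planted genes as query flags only the planted motif.
#'
#' @param seed simulation seed.
#' @param cfg configuration (defaults to `sim_config(seed = seed)`).
#' @param alpha enrichment significance threshold.
#' @return list(planted, recovered, only_planted_flagged,
#'   significant_motifs, enrichment, scan).
#' @export
motif_recovery_run <- function(seed, cfg = NULL, alpha = 6e-4) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(cfg, genome)
  plant <- simulate_pwms_and_plant_sites(cfg, genome, genes)
  scan <- motif_scan_pipeline(plant$genome, genes, plant$pwms)
  planted_motif <- plant$pwms[[1]]$id
  set_id <- paste(planted_motif, "rank", "1Kup", "conservative", sep = ".")
  target <- scan$target_sets[[set_id]]
  recovered <- intersect(plant$planted_gene_ids, target)
  universe <- scan$scores[["rank.1Kup"]]$gene_id
  enr <- suppressWarnings(
    run_enrichment(plant$planted_gene_ids, scan$target_sets, universe,
                   alpha = alpha, manifest = scan$manifest))
  sig_motifs <- unique(enr$motif[enr$significant])
  list(planted = plant$planted_gene_ids, recovered = recovered,
       only_planted_flagged = identical(sig_motifs, planted_motif),
       significant_motifs = sig_motifs, enrichment = enr, scan = scan)
}

#' Hand-evaluated 20-record filter fixture
#'
#' A built-in cohort of 18 diploid females plus one haploid male with 20
#' hand-constructed records: six fail the site hard filters (one on each
#' annotation, one triallelic, one on two annotations at once), two are
#' heterozygous in the haploid male, three fail the cohort filters (five
#' masked genotypes; a singleton below the MAF threshold; mean depth 4),
#' and nine survive -- several sitting exactly on a threshold (QD 2.0,
#' FS 60.0, MQ 40.0, ReadPosRankSum -8.0, mean DP 5.0, exactly four
#' missing genotypes) to pin the strict-inequality semantics.
#'
#' @return list(snps, expected) where `expected` holds the survivor
#'   count, surviving record ids and the per-stage removal counts.
#' @export
filter_demo_records <- function() {
  samples <- c(sprintf("F%02d", 1:18), "M01")
  nS <- length(samples)
  ids <- sprintf("r%02d", 1:20)
  base_gt <- c(1L, 1L, 2L, rep(0L, 15), 0L)  # alt dosage sum 4, MAF 1/9
  gt <- matrix(rep(base_gt, each = 20), nrow = 20,
               dimnames = list(ids, samples))
  dp <- matrix(30, 20, nS, dimnames = list(ids, samples))
  gq <- matrix(99, 20, nS, dimnames = list(ids, samples))
  sites <- data.frame(scaffold = "scafA", pos = seq(1000, 20000, by = 1000),
                      ref = "A", alt = "C", qd = 20, fs = 5, mq = 55,
                      rprs = 0, n_alt = 1L, stringsAsFactors = FALSE)
  rownames(sites) <- ids
  # six hard-filter failures
  sites["r01", "qd"] <- 1.5
  sites["r02", "fs"] <- 70
  sites["r03", "mq"] <- 35
  sites["r04", "rprs"] <- -9
  sites["r05", c("alt", "n_alt")] <- list("C,T", 2L)
  sites["r06", c("qd", "fs")] <- list(0.5, 80)
  # two haploid-heterozygous artifacts
  gt["r07", "M01"] <- 1L
  gt["r08", "M01"] <- 1L
  # three cohort failures
  dp["r09", sprintf("F%02d", 1:5)] <- 2    # 5 masked -> > 4 missing
  gt["r10", ] <- c(1L, rep(0L, 18))        # singleton, MAF 1/36 < 0.05
  dp["r11", ] <- 4                         # mean DP 4 < 5
  # boundary survivors
  sites["r12", "qd"] <- 2.0
  dp["r13", ] <- 5                         # mean DP exactly 5
  dp["r14", sprintf("F%02d", 4:7)] <- 2    # exactly 4 missing
  gt["r15", ] <- c(0L, 0L, 2L, rep(0L, 16))  # MAF 2/36 = 0.056
  sites["r16", "fs"] <- 60.0
  sites["r17", "mq"] <- 40.0
  sites["r18", "rprs"] <- -8.0
  gt["r20", "M01"] <- NA                   # missing haploid call: retained
  rownames(sites) <- NULL
  snps <- snp_set(sites, gt, dp, gq, samples, haploid = "M01")
  expected <- list(
    survivors = 9L,
    surviving_ids = sprintf("r%02d", 12:20),
    surviving_pos = seq(12000, 20000, by = 1000),
    stages = data.frame(
      stage = c("site_hard_filters", "haploid_consistency",
                "genotype_mask", "cohort_filters"),
      n_in = c(20L, 14L, 12L, 12L),
      n_removed = c(6L, 2L, 0L, 3L),
      n_out = c(14L, 12L, 12L, 9L),
      stringsAsFactors = FALSE))
  list(snps = snps, expected = expected)
}
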