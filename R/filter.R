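#' Filter-cascade configuration
#'
#' Thresholds of the two-round variant filter cascade. The defaults are
#' the final stringent pass: GATK-style site hard filters (QD < 2,
#' FS > 60, MQ < 40, ReadPosRankSum < -8, biallelic only), a
#' haploid-consistency check, genotype masking at DP < 3 or GQ < 9, and
#' cohort filters mean DP >= 5, at most 4 missing genotypes, and
#' MAF >= 0.05. All comparisons are strict on the removal side, so a
#' record sitting exactly on a threshold survives.
#'
#' @param qd_min,fs_max,mq_min,rprs_min site hard-filter thresholds.
#' @param biallelic_only drop records with more than one ALT allele.
#' @param haploid_sample haploid sample name, or NULL to skip the
#'   consistency stage.
#' @param min_mean_dp,max_missing_count,maf_min cohort-level thresholds
#'   (computed over the non-haploid samples).
#' @param gq_min,dp_min genotype-level masking thresholds (set both to 0
#'   to disable masking).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                          rprs_min = -8.0, biallelic_only = TRUE,
                          haploid_sample = NULL, min_mean_dp = 5,
                          max_missing_count = 4, maf_min = 0.05,
                          gq_min = 9, dp_min = 3) {
  cfg <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
              rprs_min = rprs_min, biallelic_only = biallelic_only,
              haploid_sample = haploid_sample, min_mean_dp = min_mean_dp,
              max_missing_count = max_missing_count, maf_min = maf_min,
              gq_min = gq_min, dp_min = dp_min)
  num <- unlist(cfg[c("qd_min", "fs_max", "mq_min", "rprs_min",
                      "min_mean_dp", "max_missing_count", "maf_min",
                      "gq_min", "dp_min")])
  if (any(!is.finite(num))) stop("thresholds must be finite")
  if (cfg$maf_min < 0 || cfg$maf_min > 0.5)
    stop("maf_min must lie in [0, 0.5]")
  class(cfg) <- "filter_config"
  cfg
}

#' Named filter presets for the two calling rounds
#'
#' `round1`: hard filters + haploid consistency + zero missing genotypes
#' (the high-confidence set used for recalibration). `round2_gatk`: hard
#' filters + haploid consistency, allowing up to 8 missing genotypes.
#' `round2_final`: the full stringent pass (the default
#' [filter_config()]).
#'
#' @param name one of "round1", "round2_gatk", "round2_final".
#' @param haploid_sample haploid sample name passed through.
#' @return a [filter_config()].
#' @export
filter_preset <- function(name = c("round2_final", "round1", "round2_gatk"),
                          haploid_sample = NULL) {
  name <- match.arg(name)
  switch(name,
    round1 = filter_config(haploid_sample = haploid_sample,
                           min_mean_dp = 0, max_missing_count = 0,
                           maf_min = 0, gq_min = 0, dp_min = 0),
    round2_gatk = filter_config(haploid_sample = haploid_sample,
                                min_mean_dp = 0, max_missing_count = 8,
                                maf_min = 0, gq_min = 0, dp_min = 0),
    round2_final = filter_config(haploid_sample = haploid_sample))
}

new_report <- function(stage, n_in, n_removed, reasons = NULL) {
  stages <- data.frame(stage = stage, n_in = n_in, n_removed = n_removed,
                       n_out = n_in - n_removed, stringsAsFactors = FALSE)
  if (is.null(reasons))
    reasons <- data.frame(stage = character(), reason = character(),
                          count = integer(), stringsAsFactors = FALSE)
  structure(list(stages = stages, reasons = reasons),
            class = "filter_report")
}

reason_df <- function(stage, counts) {
  counts <- counts[counts > 0]
  data.frame(stage = rep(stage, length(counts)), reason = names(counts),
             count = as.integer(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

bind_reports <- function(...) {
  reps <- list(...)
  structure(list(stages = do.call(rbind, lapply(reps, `[[`, "stages")),
                 reasons = do.call(rbind, lapply(reps, `[[`, "reasons"))),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  print(x$stages, row.names = FALSE)
  if (nrow(x$reasons)) {
    cat("reasons:\n")
    print(x$reasons, row.names = FALSE)
  }
  invisible(x)
}

#' Site-level hard filters
#'
#' A record survives iff QD >= qd_min, FS <= fs_max, MQ >= mq_min,
#' ReadPosRankSum >= rprs_min and (when `biallelic_only`) it has exactly
#' one ALT allele. A missing annotation passes its predicate (the GATK
#' VariantFiltration convention) and is counted in the report.
#'
#' @param snps a [snp_set()].
#' @param cfg a [filter_config()].
#' @return list(snps = surviving records, report = [filter_report]).
#' @export
apply_site_hard_filters <- function(snps, cfg) {
  s <- snps$sites
  pass_na <- function(x, pred) is.na(x) | pred(x)
  ok_qd <- pass_na(s$qd, function(x) x >= cfg$qd_min)
  ok_fs <- pass_na(s$fs, function(x) x <= cfg$fs_max)
  ok_mq <- pass_na(s$mq, function(x) x >= cfg$mq_min)
  ok_rprs <- pass_na(s$rprs, function(x) x >= cfg$rprs_min)
  ok_allele <- if (isTRUE(cfg$biallelic_only)) s$n_alt == 1L else TRUE
  keep <- ok_qd & ok_fs & ok_mq & ok_rprs & ok_allele
  reasons <- reason_df("site_hard_filters", c(
    qd = sum(!ok_qd), fs = sum(!ok_fs), mq = sum(!ok_mq),
    rprs = sum(!ok_rprs), multiallelic = sum(!ok_allele),
    missing_info = sum(is.na(s$qd)) + sum(is.na(s$fs)) +
      sum(is.na(s$mq)) + sum(is.na(s$rprs))))
  list(snps = subset_snp_set(snps, keep),
       report = new_report("site_hard_filters", nrow(s), sum(!keep),
                           reasons))
}

#' Haploid-consistency filter
#'
#' A haploid individual cannot be heterozygous: records where the haploid
#' sample's genotype is heterozygous are genotyping artifacts and are
#' removed. A missing haploid genotype retains the record (counted).
#'
#' @param snps a [snp_set()].
#' @param haploid_sample sample name; must exist in the set.
#' @return list(snps, report).
#' @export
apply_haploid_consistency <- function(snps, haploid_sample) {
  if (!haploid_sample %in% snps$samples)
    stop("unknown haploid sample: ", haploid_sample)
  g <- snps$gt[, haploid_sample]
  het <- !is.na(g) & g == 1L
  reasons <- reason_df("haploid_consistency",
                       c(haploid_het = sum(het),
                         haploid_missing = sum(is.na(g))))
  list(snps = subset_snp_set(snps, !het),
       report = new_report("haploid_consistency", length(g), sum(het),
                           reasons))
}

#' Genotype-level DP/GQ masking
#'
#' Sets a genotype to missing iff DP < dp_min or GQ < gq_min (an absent
#' DP or GQ value is treated as failing). No records are removed at this
#' stage; sites that lose all their genotypes fall to the cohort filters.
#' With both thresholds at 0 the stage is a no-op.
#'
#' @param snps a [snp_set()].
#' @param cfg a [filter_config()].
#' @return list(snps = set with masked genotypes, report).
#' @export
apply_genotype_filters <- function(snps, cfg) {
  m <- nrow(snps$sites)
  if (cfg$dp_min <= 0 && cfg$gq_min <= 0)
    return(list(snps = snps,
                report = new_report("genotype_mask", m, 0L)))
  fail <- (is.na(snps$dp) | snps$dp < cfg$dp_min) |
    (is.na(snps$gq) | snps$gq < cfg$gq_min)
  mask <- fail & !is.na(snps$gt)
  gt <- snps$gt
  gt[mask] <- NA_integer_
  out <- snp_set(snps$sites, gt, snps$dp, snps$gq, snps$samples,
                 snps$haploid, snps$gt_str)
  list(snps = out,
       report = new_report("genotype_mask", m, 0L,
                           reason_df("genotype_mask",
                                     c(genotypes_masked = sum(mask)))))
}

#' Cohort-level filters
#'
#' Computed over the non-haploid samples, after genotype masking: a site
#' survives iff the mean DP over called genotypes is >= min_mean_dp, at
#' most `max_missing_count` genotypes are missing, and the minor-allele
#' frequency from the called dosages is >= maf_min. A site with zero
#' called genotypes is removed with reason "all_missing".
#'
#' @param snps a [snp_set()].
#' @param cfg a [filter_config()].
#' @return list(snps, report).
#' @export
apply_cohort_filters <- function(snps, cfg) {
  m <- nrow(snps$sites)
  cohort <- snps$samples
  hap <- if (!is.null(cfg$haploid_sample)) cfg$haploid_sample else
    snps$haploid
  if (!is.null(hap)) cohort <- setdiff(cohort, hap)
  gt <- snps$gt[, cohort, drop = FALSE]
  dp <- snps$dp[, cohort, drop = FALSE]
  called <- !is.na(gt)
  n_called <- rowSums(called)
  n_missing <- length(cohort) - n_called
  dpc <- dp
  dpc[!called] <- NA
  mean_dp <- rowMeans(dpc, na.rm = TRUE)
  alt_sum <- rowSums(gt, na.rm = TRUE)
  f <- ifelse(n_called > 0, alt_sum / (2 * n_called), NA)
  maf <- pmin(f, 1 - f)
  all_missing <- n_called == 0
  ok_dp <- !all_missing & !is.na(mean_dp) & mean_dp >= cfg$min_mean_dp
  ok_miss <- n_missing <= cfg$max_missing_count
  ok_maf <- !all_missing & maf >= cfg$maf_min
  keep <- ok_dp & ok_miss & ok_maf & !all_missing
  reasons <- reason_df("cohort_filters", c(
    mean_dp = sum(!ok_dp & !all_missing), missingness = sum(!ok_miss),
    maf = sum(!ok_maf & !all_missing), all_missing = sum(all_missing)))
  list(snps = subset_snp_set(snps, keep),
       report = new_report("cohort_filters", m, sum(!keep), reasons))
}

#' Run the full filter cascade
#'
#' Stage order: site hard filters -> haploid consistency -> genotype
#' masking -> cohort filters. Input can be a [snp_set()] or a VCF path;
#' optionally writes the surviving records as VCF (masked genotypes
#' written missing) and the per-stage report as TSV.
#'
#' @param x a [snp_set()] or a VCF file path.
#' @param cfg a [filter_config()].
#' @param out optional output VCF path.
#' @param report optional output report TSV path.
#' @return list(snps, report).
#' @export
run_filter_cascade <- function(x, cfg = filter_config(), out = NULL,
                               report = NULL) {
  snps <- if (inherits(x, "snp_set")) x else
    read_vcf(x, haploid = cfg$haploid_sample)
  hap <- if (!is.null(cfg$haploid_sample)) cfg$haploid_sample else
    snps$haploid
  st1 <- apply_site_hard_filters(snps, cfg)
  if (!is.null(hap)) {
    st2 <- apply_haploid_consistency(st1$snps, hap)
  } else {
    st2 <- list(snps = st1$snps,
                report = new_report("haploid_consistency",
                                    n_sites(st1$snps), 0L))
  }
  st3 <- apply_genotype_filters(st2$snps, cfg)
  st4 <- apply_cohort_filters(st3$snps, cfg)
  rep_all <- bind_reports(st1$report, st2$report, st3$report, st4$report)
  if (!is.null(out)) write_vcf(st4$snps, out)
  if (!is.null(report))
    write.table(rep_all$stages, report, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(snps = st4$snps, report = rep_all)
}
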