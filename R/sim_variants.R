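#' Simulate cohort variants with planted sweeps
#'
#' Places biallelic SNPs along the genome by a Poisson process and draws,
#' for each site, a derived-allele count `i` from the neutral site
#' frequency spectrum (probability proportional to `1/i` over
#' `i = 1..C-1`, `C` = total chromosomes). The `i` derived copies are
#' assigned to chromosomes uniformly at random and chromosomes are paired
#' into diploid genotypes (random union of gametes), so the sample SFS is
#' exact by construction. The per-bp site rate is
#' `theta_per_bp * a1(C)` with `a1` the harmonic number: under the 1/i
#' spectrum the expected per-site heterozygosity is exactly `1/a1(C)`,
#' which makes the expected windowed pi equal `theta_per_bp` and centres
#' the Tajima's D numerator at zero on neutral sequence.
#'
#' Inside `cfg$sweep_regions` the site density is multiplied by
#' `diversity_reduction` and counts are drawn with probability
#' proportional to `1/i^sfs_skew`, skewing the spectrum toward rare
#' alleles -- the low-pi / negative-D signature of a selective sweep.
#'
#' The haploid sample carries a single chromosome but is written as a
#' homozygous diploid genotype (as a ploidy-2 caller would emit it),
#' except for a fraction `haploid_error_fraction` of sites written
#' heterozygous to exercise the haploid-consistency filter. Site
#' annotations QD/FS/MQ/ReadPosRankSum are drawn from passing
#' distributions except for `bad_site_fraction` of sites, which get one
#' failing annotation.
#'
#' @param cfg a [sim_config()].
#' @param genome genome from [simulate_genome()].
#' @param genes gene models from [simulate_gene_models()]; used only to
#'   record which genes fall in sweep regions in the truth table.
#' @return list with elements `snps` (a [snp_set()]) and `truth` (list
#'   with `site_freq` data.frame, `sweep_gene_ids`, and the sweep layout).
#' @export
simulate_variants <- function(cfg, genome, genes = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_diploid < 2) stop("n_diploid must be >= 2")
  sl <- setNames(Biostrings::width(genome), names(genome))
  sw <- cfg$sweep_regions
  if (!is.null(sw)) {
    bad <- !(sw$scaffold %in% names(sl)) | sw$end > sl[sw$scaffold]
    if (any(bad)) stop("sweep region outside genome")
  }
  C <- 2L * cfg$n_diploid + cfg$n_haploid
  a1 <- sum(1 / seq_len(C - 1))
  rate <- cfg$theta_per_bp * a1

  set.seed(op_seed(cfg$seed, 4L))
  site_list <- list()
  for (scaf in names(sl)) {
    L <- sl[[scaf]]
    # density multiplier per base: 1 outside sweeps, reduction inside
    mult <- rep(1, L)
    skew <- rep(1, L)
    if (!is.null(sw)) {
      for (j in which(sw$scaffold == scaf)) {
        idx <- seq.int(sw$start[j] + 1, sw$end[j])
        mult[idx] <- sw$diversity_reduction[j]
        skew[idx] <- sw$sfs_skew[j]
      }
    }
    n_exp <- rate * sum(mult)
    n <- rpois(1, n_exp)
    if (n == 0) next
    pos <- sort(sample.int(L, size = min(n, L), prob = mult))
    site_list[[scaf]] <- data.frame(scaffold = scaf, pos = pos,
                                    sfs_skew = skew[pos],
                                    in_sweep = mult[pos] < 1,
                                    stringsAsFactors = FALSE)
  }
  sites <- if (length(site_list)) do.call(rbind, site_list) else
    data.frame(scaffold = character(), pos = integer(),
               sfs_skew = numeric(), in_sweep = logical())
  rownames(sites) <- NULL
  m <- nrow(sites)

  n_samp <- cfg$n_diploid + cfg$n_haploid
  samples <- c(sprintf("F%02d", seq_len(cfg$n_diploid)),
               if (cfg$n_haploid > 0) sprintf("M%02d", seq_len(cfg$n_haploid)))
  haploid <- if (cfg$n_haploid > 0) samples[cfg$n_diploid + 1L] else NULL

  gt <- matrix(0L, nrow = m, ncol = n_samp, dimnames = list(NULL, samples))
  derived_count <- integer(m)
  ivals <- seq_len(C - 1)
  if (m > 0) {
    # derived counts: 1/i^skew spectrum, one draw per site
    for (s in unique(sites$sfs_skew)) {
      idx <- which(sites$sfs_skew == s)
      w <- 1 / ivals^s
      derived_count[idx] <- sample(ivals, length(idx), replace = TRUE,
                                   prob = w / sum(w))
    }
    for (k in seq_len(m)) {
      der <- sample.int(C, derived_count[k])
      dip <- der[der <= 2L * cfg$n_diploid]
      if (length(dip))
        gt[k, seq_len(cfg$n_diploid)] <-
          tabulate((dip + 1L) %/% 2L, nbins = cfg$n_diploid)
      if (cfg$n_haploid > 0) {
        hap_der <- der[der > 2L * cfg$n_diploid] - 2L * cfg$n_diploid
        if (length(hap_der))
          gt[k, cfg$n_diploid + hap_der] <- 2L
      }
    }
    if (cfg$n_haploid > 0 && cfg$haploid_error_fraction > 0) {
      err <- runif(m) < cfg$haploid_error_fraction
      for (h in seq_len(cfg$n_haploid)) gt[err, cfg$n_diploid + h] <- 1L
    }
  }

  # ref/alt alleles from the reference base
  ref <- alt <- character(m)
  if (m > 0) {
    for (scaf in unique(sites$scaffold)) {
      idx <- which(sites$scaffold == scaf)
      b <- strsplit(as.character(Biostrings::extractAt(
        genome[[scaf]], IRanges::IRanges(sites$pos[idx], width = 1))),
        "")
      ref[idx] <- unlist(b)
    }
    others <- lapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r))
    alt <- vapply(others, function(o) sample(o, 1), character(1))
  }

  # site annotations: passing by default, bad_site_fraction get one failure
  qd <- runif(m, 10, 35)
  fs <- runif(m, 0, 10)
  mq <- runif(m, 50, 60)
  rprs <- runif(m, -2, 2)
  if (m > 0 && cfg$bad_site_fraction > 0) {
    bad <- which(runif(m) < cfg$bad_site_fraction)
    which_ann <- sample(4, length(bad), replace = TRUE)
    qd[bad[which_ann == 1]] <- runif(sum(which_ann == 1), 0, 1.9)
    fs[bad[which_ann == 2]] <- runif(sum(which_ann == 2), 61, 120)
    mq[bad[which_ann == 3]] <- runif(sum(which_ann == 3), 20, 39.5)
    rprs[bad[which_ann == 4]] <- runif(sum(which_ann == 4), -20, -8.1)
  }

  # per-genotype depth and quality
  lambda <- rep(cfg$coverage_mean, m)
  dips <- cfg$coverage_dip_regions
  if (!is.null(dips) && m > 0) {
    for (j in seq_len(nrow(dips))) {
      hit <- sites$scaffold == dips$scaffold[j] &
        sites$pos > dips$start[j] & sites$pos <= dips$end[j]
      lambda[hit] <- cfg$coverage_dip_mean
    }
  }
  dp <- matrix(rpois(m * n_samp, rep(lambda, n_samp)), nrow = m,
               dimnames = list(NULL, samples))
  gq <- matrix(pmin(99L, rpois(m * n_samp, 60)), nrow = m,
               dimnames = list(NULL, samples))
  if (m > 0 && cfg$low_gq_fraction > 0) {
    low <- runif(m * n_samp) < cfg$low_gq_fraction
    gq[low] <- sample(0:8, sum(low), replace = TRUE)
  }

  site_df <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                        ref = ref, alt = alt,
                        qd = qd, fs = fs, mq = mq, rprs = rprs,
                        n_alt = rep(1L, m), stringsAsFactors = FALSE)
  snps <- snp_set(site_df, gt, dp, gq, samples, haploid = haploid)

  sweep_gene_ids <- character(0)
  if (!is.null(sw) && !is.null(genes)) {
    hit <- vapply(seq_len(nrow(genes)), function(i) {
      any(sw$scaffold == genes$scaffold[i] &
            sw$start < genes$end[i] & sw$end > genes$start[i])
    }, logical(1))
    sweep_gene_ids <- genes$gene_id[hit]
  }
  truth <- list(site_freq = data.frame(scaffold = sites$scaffold,
                                       pos = sites$pos,
                                       derived_count = derived_count,
                                       n_chrom = rep(C, m),
                                       in_sweep = sites$in_sweep,
                                       stringsAsFactors = FALSE),
                sweep_gene_ids = sweep_gene_ids,
                sweep_regions = sw)
  list(snps = snps, truth = truth)
}

#' Write a truth table as TSV
#' @param truth truth list from [simulate_variants()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth$site_freq, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
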