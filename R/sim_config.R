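#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic-data module. The defaults are the
#' study conditions the rest of the package is exercised under: a cohort of
#' 18 diploid females plus one haploid male, genome-wide diversity around
#' 1.5e-3 per bp, 30x coverage, and genes laid out on a regular grid with
#' enough intergenic room for 1 kb promoters.
#'
#' @param seed integer seed; the same configuration always produces
#'   byte-identical outputs.
#' @param genome_length total genome size in bp (>= 10 kb).
#' @param n_scaffolds number of scaffolds the genome is split into.
#' @param gc_mean target GC fraction of the simulated genome.
#' @param n_genes number of gene models.
#' @param gene_length length of each gene model in bp.
#' @param n_diploid,n_haploid cohort composition (diploid females, haploid
#'   males).
#' @param theta_per_bp expected pairwise nucleotide diversity per bp outside
#'   sweep regions.
#' @param sweep_regions data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open), `diversity_reduction` in (0,1) and `sfs_skew`
#'   (>= 1), or NULL for a fully neutral genome.
#' @param coverage_mean mean read depth per site.
#' @param coverage_dip_regions data.frame with `scaffold`, `start`, `end`
#'   for low-coverage intervals, or NULL.
#' @param coverage_dip_mean mean depth inside dip regions.
#' @param n_motifs number of PWMs in the simulated motif collection.
#' @param motif_length PWM width in bp (>= 6).
#' @param pwm_dominance probability of the consensus base in each PWM
#'   column before the scoring pseudocount; the default 1 gives
#'   degenerate 2-bit-per-column motifs whose planted sites equal the
#'   consensus (the strong-information-content planting condition the
#'   recovery experiments are defined under).
#' @param planted_gene_fraction fraction of genes that receive a planted
#'   site of the first motif in their 1 kb upstream region.
#' @param bad_site_fraction fraction of variant sites given a failing
#'   QD/FS/MQ/ReadPosRankSum annotation.
#' @param haploid_error_fraction fraction of sites at which the haploid
#'   sample is (erroneously) written heterozygous.
#' @param low_gq_fraction fraction of genotypes given a low (< 9) GQ.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_scaffolds = 4L,
                       gc_mean = 0.37,
                       n_genes = 400L,
                       gene_length = 2000L,
                       n_diploid = 18L,
                       n_haploid = 1L,
                       theta_per_bp = 0.0015,
                       sweep_regions = NULL,
                       coverage_mean = 30,
                       coverage_dip_regions = NULL,
                       coverage_dip_mean = 2,
                       n_motifs = 8L,
                       motif_length = 8L,
                       pwm_dominance = 1.0,
                       planted_gene_fraction = 0.05,
                       bad_site_fraction = 0.02,
                       haploid_error_fraction = 0.01,
                       low_gq_fraction = 0.01) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.numeric(genome_length),
              n_scaffolds = as.integer(n_scaffolds),
              gc_mean = gc_mean,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              n_diploid = as.integer(n_diploid),
              n_haploid = as.integer(n_haploid),
              theta_per_bp = theta_per_bp,
              sweep_regions = sweep_regions,
              coverage_mean = coverage_mean,
              coverage_dip_regions = coverage_dip_regions,
              coverage_dip_mean = coverage_dip_mean,
              n_motifs = as.integer(n_motifs),
              motif_length = as.integer(motif_length),
              pwm_dominance = pwm_dominance,
              planted_gene_fraction = planted_gene_fraction,
              bad_site_fraction = bad_site_fraction,
              haploid_error_fraction = haploid_error_fraction,
              low_gq_fraction = low_gq_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.finite(cfg$seed), abs(cfg$seed) < 2^31 - 100)
  counts <- c(cfg$n_scaffolds, cfg$n_genes, cfg$n_diploid, cfg$n_haploid,
              cfg$n_motifs)
  if (any(counts < 0)) stop("counts must be >= 0")
  fracs <- c(cfg$gc_mean, cfg$planted_gene_fraction, cfg$bad_site_fraction,
             cfg$haploid_error_fraction, cfg$low_gq_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$genome_length < 1e4) stop("genome_length must be >= 10 kb")
  if (cfg$n_scaffolds >= 1 && cfg$genome_length / cfg$n_scaffolds < 1)
    stop("zero-length scaffold request")
  if (!is.null(cfg$sweep_regions)) {
    sw <- cfg$sweep_regions
    stopifnot(is.data.frame(sw),
              all(c("scaffold", "start", "end",
                    "diversity_reduction", "sfs_skew") %in% names(sw)))
    if (any(sw$start < 0 | sw$end <= sw$start))
      stop("malformed sweep interval")
    if (any(sw$diversity_reduction <= 0 | sw$diversity_reduction >= 1))
      stop("diversity_reduction must lie in (0, 1)")
    if (any(sw$sfs_skew < 1)) stop("sfs_skew must be >= 1")
  }
  if (cfg$theta_per_bp <= 0) stop("theta_per_bp must be positive")
  if (cfg$motif_length < 1) stop("motif_length must be >= 1")
  invisible(cfg)
}

# Deterministic per-operation seed so each generator stage is independently
# reproducible no matter in which order stages are called.
op_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k) %% 2147483629)
}

#' Scaffold lengths implied by a configuration
#'
#' The genome is split into near-equal scaffolds (remainder bp go to the
#' first scaffold), deterministically.
#' @param cfg a [sim_config()].
#' @return named integer vector of scaffold lengths.
#' @export
scaffold_lengths <- function(cfg) {
  n <- cfg$n_scaffolds
  base <- floor(cfg$genome_length / n)
  if (base < 1) stop("zero-length scaffold request")
  len <- rep(base, n)
  len[1] <- len[1] + (cfg$genome_length - base * n)
  names(len) <- sprintf("scaf%02d", seq_len(n))
  len
}
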