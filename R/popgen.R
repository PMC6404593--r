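#' Per-site nucleotide diversity
#'
#' The unbiased per-site heterozygosity `2 j (n - j) / (n (n - 1))` for
#' `j` alternate alleles among `n` called alleles (the vcftools
#' `--site-pi` quantity). Vectorised; returns NA (undefined, distinct
#' from 0) where `n < 2`.
#'
#' @param n_called_alleles number of called alleles at the site.
#' @param alt_count number of alternate alleles (0..n).
#' @return numeric vector of per-site pi.
#' @export
site_pi <- function(n_called_alleles, alt_count) {
  n <- n_called_alleles
  j <- alt_count
  if (any(j < 0 | j > n, na.rm = TRUE))
    stop("alt_count must lie in [0, n_called_alleles]")
  out <- 2 * j * (n - j) / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

#' Tajima's D normalising constants
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 constants for a sample of `n`
#' chromosomes, as defined in the classical derivation of the D
#' statistic.
#'
#' @param n number of sampled chromosomes (>= 2).
#' @return named numeric vector.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need at least 2 chromosomes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1,
    e2 = e2)
}

#' Tajima's D for one window of genotypes
#'
#' `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))`, where `pi_sum` is
#' the window's sum of per-site pairwise-difference averages and `S` the
#' number of segregating sites. Missing genotypes are handled by using
#' the called-allele count at each site; the `n` for the constants is the
#' median per-site called-allele count over the window's sites (rounded).
#' Undefined (NA) when `S = 0`, never 0.
#'
#' @param gt dosage matrix (sites x diploid samples) for the window, NA =
#'   missing.
#' @return Tajima's D, or NA when no site segregates.
#' @export
window_tajimas_d <- function(gt) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  if (nrow(gt) == 0) return(NA_real_)
  n_called <- 2 * rowSums(!is.na(gt))
  j <- rowSums(gt, na.rm = TRUE)
  use <- n_called >= 2
  if (!any(use)) return(NA_real_)
  n_called <- n_called[use]
  j <- j[use]
  seg <- j > 0 & j < n_called
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_sum <- sum(site_pi(n_called, j))
  n <- round(median(n_called))
  cst <- tajima_constants(n)
  (pi_sum - S / cst[["a1"]]) /
    sqrt(cst[["e1"]] * S + cst[["e2"]] * S * (S - 1))
}

tile_windows <- function(lengths, window) {
  if (window < 1) stop("window length must be >= 1")
  out <- lapply(names(lengths), function(scaf) {
    L <- lengths[[scaf]]
    if (L == 0) return(NULL)
    starts <- seq.int(0L, L - 1L, by = window)
    data.frame(scaffold = scaf, start = starts,
               end = pmin(starts + window, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$partial <- (out$end - out$start) < window
  out
}

#' Windowed diversity statistics
#'
#' Tiles each scaffold into non-overlapping windows anchored at position
#' 0 (trailing partial windows kept and flagged) and computes, per
#' window: the number of variant sites, segregating sites S, uncorrected
#' pi (pairwise-difference sum divided by the window length), the
#' coverage-corrected pi (divided by the *count* of sites with depth >=
#' `min_depth`, from the coverage track), Tajima's D, the covered
#' fraction and optionally GC. Statistics are computed over the diploid
#' cohort: the haploid sample, if present, is excluded.
#'
#' @param snps a [snp_set()].
#' @param genome a DNAStringSet, or a named vector of scaffold lengths
#'   (GC is then not reported).
#' @param window window size in bp (1000 or 10000 in typical use).
#' @param coverage optional coverage data.frame
#'   (scaffold, start, end, fraction) on the same window grid.
#' @param min_depth depth threshold the coverage track was computed at.
#' @return data.frame of per-window statistics; undefined values are NA.
#' @export
windowed_diversity <- function(snps, genome, window = 1000L,
                               coverage = NULL, min_depth = 5L) {
  if (inherits(genome, "DNAStringSet")) {
    lengths <- setNames(Biostrings::width(genome), names(genome))
  } else {
    lengths <- genome
    genome <- NULL
  }
  win <- tile_windows(lengths, window)
  cohort <- setdiff(snps$samples, snps$haploid)
  gt <- snps$gt[, cohort, drop = FALSE]
  s <- snps$sites

  key <- paste(win$scaffold, win$start)
  site_key <- paste(s$scaffold, ((s$pos - 1L) %/% window) * window)
  idx <- match(site_key, key)

  n_called <- 2 * rowSums(!is.na(gt))
  j <- rowSums(gt, na.rm = TRUE)
  pi_site <- site_pi(pmax(n_called, 0), j)
  seg <- !is.na(pi_site) & j > 0 & j < n_called

  nw <- nrow(win)
  win$n_sites <- tabulate(idx, nbins = nw)
  win$S <- tabulate(idx[seg], nbins = nw)
  pi_ok <- !is.na(pi_site)
  pi_sum <- rep(0, nw)
  agg <- tapply(pi_site[pi_ok], idx[pi_ok], sum)
  pi_sum[as.integer(names(agg))] <- agg
  win$pi_sum <- pi_sum
  win$pi <- pi_sum / (win$end - win$start)

  if (!is.null(coverage)) {
    ckey <- paste(coverage$scaffold, coverage$start)
    win$covered_fraction <- coverage$fraction[match(key, ckey)]
  } else {
    win$covered_fraction <- NA_real_
  }
  n_covered <- ifelse(is.na(win$covered_fraction),
                      win$end - win$start,
                      round(win$covered_fraction * (win$end - win$start)))
  win$pi_corrected <- ifelse(n_covered > 0, pi_sum / n_covered, NA_real_)

  win$tajimas_d <- NA_real_
  has_seg <- which(win$S > 0)
  for (k in has_seg) {
    rows <- which(idx == k)
    win$tajimas_d[k] <- window_tajimas_d(gt[rows, , drop = FALSE])
  }

  if (!is.null(genome)) {
    win$gc <- NA_real_
    for (scaf in names(genome)) {
      rows <- which(win$scaffold == scaf)
      if (!length(rows)) next
      v <- Biostrings::Views(genome[[scaf]],
                             start = win$start[rows] + 1L,
                             end = win$end[rows])
      f <- Biostrings::letterFrequency(v, c("G", "C"))
      win$gc[rows] <- rowSums(f) / (win$end[rows] - win$start[rows])
    }
  }
  win$pi_sum <- NULL
  win
}

#' Per-individual heterozygosity and inbreeding coefficient
#'
#' For each diploid sample, over its called sites: the observed
#' homozygote count O, the expected homozygote count
#' `E = sum(1 - 2 p q 2n/(2n-1))` with `p` the cohort allele frequency
#' and `n` the called diploid count at the site, and the inbreeding
#' coefficient `F = (O - E) / (N - E)` (the vcftools `--het`
#' statistics).
#'
#' @param gt dosage matrix (sites x diploid samples).
#' @return data.frame(sample, observed_hom, expected_hom, n_sites, F).
#' @export
individual_heterozygosity <- function(gt) {
  if (ncol(gt) < 2) stop("need at least 2 samples")
  called <- !is.na(gt)
  n <- rowSums(called)
  p <- rowSums(gt, na.rm = TRUE) / (2 * n)
  exp_hom_site <- 1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  use <- n >= 2 & p > 0 & p < 1
  out <- lapply(colnames(gt), function(smp) {
    rows <- use & called[, smp]
    O <- sum(gt[rows, smp] != 1)
    E <- sum(exp_hom_site[rows])
    N <- sum(rows)
    data.frame(sample = smp, observed_hom = O, expected_hom = E,
               n_sites = N,
               F = if (N > E) (O - E) / (N - E) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities follow the standard recurrence over heterozygote counts
#' of equal parity. A monomorphic site gives p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1.0)
  hets <- seq.int(rare %% 2, rare, by = 2)
  # unnormalised log-probabilities by the upward recurrence
  # P(h+2)/P(h) = 4 hom_rare(h) hom_common(h) / ((h+1)(h+2))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h0 <- hets[k - 1]
    hom_r <- (rare - h0) / 2
    hom_c <- n - h0 - hom_r
    lp[k] <- lp[k - 1] + log(4 * hom_r * hom_c) -
      log((h0 + 1) * (h0 + 2))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Pairwise relatedness (unadjusted Ajk)
#'
#' Yang's moment estimator from genotype dosages and in-sample allele
#' frequencies: off-diagonal
#' `Ajk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))` and
#' diagonal
#' `Ajj = 1 + mean_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`.
#' Sites monomorphic in the matrix are excluded from the site count m;
#' for pairs with missing data the mean runs over sites where both
#' genotypes are called.
#'
#' @param gt dosage matrix (sites x diploid samples).
#' @return list with `samples`, the symmetric `ajk` matrix, and
#'   `n_sites_used`.
#' @export
relatedness_ajk <- function(gt) {
  if (ncol(gt) < 2) stop("need at least 2 diploid samples")
  called <- !is.na(gt)
  n <- rowSums(called)
  p <- rowSums(gt, na.rm = TRUE) / (2 * n)
  use <- n >= 1 & p > 0 & p < 1
  if (!any(use)) stop("no polymorphic sites usable for Ajk")
  x <- gt[use, , drop = FALSE]
  p <- p[use]
  denom <- 2 * p * (1 - p)
  z <- (x - 2 * p) / sqrt(denom)
  z0 <- z
  z0[is.na(z0)] <- 0
  pair_m <- crossprod(!is.na(z))
  A <- crossprod(z0) / pair_m
  # diagonal by its own formula
  diag_term <- (x^2 - (1 + 2 * p) * x + 2 * p^2) / denom
  diag(A) <- 1 + colMeans(diag_term, na.rm = TRUE)
  list(samples = colnames(gt), ajk = A, n_sites_used = nrow(x))
}

#' Write windowed statistics as TSV (undefined values as "nan")
#' @param win data.frame from [windowed_diversity()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_windows_tsv <- function(win, path) {
  out <- win
  for (cl in names(out))
    if (is.numeric(out[[cl]])) out[[cl]][is.na(out[[cl]])] <- NaN
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
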