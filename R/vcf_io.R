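#' A per-site genotype container
#'
#' The substrate of the filter cascade and the population statistics: one
#' row per variant site with its hard-filter annotations, plus aligned
#' sites x samples matrices of genotype dosage (0/1/2, NA = missing),
#' depth and genotype quality. Dosage counts non-reference alleles, so it
#' extends to multiallelic records; an optional `gt_str` matrix preserves
#' the original VCF genotype strings for faithful round-tripping.
#'
#' @param sites data.frame with columns scaffold, pos (1-based), ref, alt
#'   (comma-separated for multiallelic), qd, fs, mq, rprs (NA when the
#'   annotation is absent), n_alt.
#' @param gt integer dosage matrix, sites x samples.
#' @param dp,gq integer matrices of per-genotype depth and quality.
#' @param samples sample names (column order of the matrices).
#' @param haploid name of the haploid sample, or NULL.
#' @param gt_str optional character matrix of raw GT strings.
#' @return an object of class `snp_set`.
#' @export
snp_set <- function(sites, gt, dp, gq, samples, haploid = NULL,
                    gt_str = NULL) {
  m <- nrow(sites)
  stopifnot(nrow(gt) == m, nrow(dp) == m, nrow(gq) == m,
            ncol(gt) == length(samples), ncol(dp) == length(samples),
            ncol(gq) == length(samples))
  if (!is.null(haploid) && !haploid %in% samples)
    stop("haploid sample '", haploid, "' not among the samples")
  if (m > 0 && any(sites$pos < 1)) stop("positions must be >= 1")
  colnames(gt) <- colnames(dp) <- colnames(gq) <- samples
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq,
                 samples = samples, haploid = haploid, gt_str = gt_str),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set:", nrow(x$sites), "sites x", length(x$samples), "samples",
      if (!is.null(x$haploid)) paste0("(haploid: ", x$haploid, ")"), "\n")
  invisible(x)
}

#' Number of sites in a snp_set
#' @param snps a [snp_set()].
#' @return integer site count.
#' @export
n_sites <- function(snps) nrow(snps$sites)

subset_snp_set <- function(snps, keep) {
  snp_set(snps$sites[keep, , drop = FALSE],
          snps$gt[keep, , drop = FALSE],
          snps$dp[keep, , drop = FALSE],
          snps$gq[keep, , drop = FALSE],
          snps$samples, snps$haploid,
          if (!is.null(snps$gt_str)) snps$gt_str[keep, , drop = FALSE])
}

#' Read a VCF into a snp_set
#'
#' Parses a VCF v4.2 file via vcfR and extracts the QD/FS/MQ/
#' ReadPosRankSum site annotations and GT/DP/GQ genotype fields. A
#' genotype is missing (dosage NA) iff any of its alleles is '.'.
#'
#' @param path VCF file (plain or gzipped).
#' @param haploid optional haploid sample name.
#' @return a [snp_set()].
#' @export
read_vcf <- function(path, haploid = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  m <- nrow(fix)
  if (is.null(m)) m <- 0L
  if (m == 0) {
    samples <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    empty <- matrix(integer(0), 0, length(samples))
    return(snp_set(data.frame(scaffold = character(), pos = integer(),
                              ref = character(), alt = character(),
                              qd = numeric(), fs = numeric(),
                              mq = numeric(), rprs = numeric(),
                              n_alt = integer()),
                   empty, empty, empty, samples, haploid))
  }
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  alt <- fix[, "ALT"]
  sites <- data.frame(scaffold = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = alt,
                      qd = info_num("QD"), fs = info_num("FS"),
                      mq = info_num("MQ"), rprs = info_num("ReadPosRankSum"),
                      n_alt = lengths(strsplit(ifelse(alt == ".", "", alt),
                                               ",", fixed = TRUE)),
                      stringsAsFactors = FALSE)
  gt_str <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_str)
  dosage <- gt_to_dosage(gt_str)
  num_mat <- function(el) {
    x <- suppressWarnings(
      vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    if (is.null(x)) matrix(NA_real_, m, length(samples)) else x
  }
  snp_set(sites, dosage, num_mat("DP"), num_mat("GQ"), samples,
          haploid = haploid, gt_str = gt_str)
}

gt_to_dosage <- function(gt_str) {
  u <- unique(as.vector(gt_str))
  dose <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  out <- matrix(dose[match(as.vector(gt_str), u)], nrow = nrow(gt_str),
                dimnames = dimnames(gt_str))
  out
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "0/1"
  out[!is.na(d) & d == 2] <- "1/1"
  out
}

#' Write a snp_set as VCF v4.2
#'
#' Emits a minimal but standard-compliant plain-text VCF with the
#' QD/FS/MQ/ReadPosRankSum INFO keys and GT:DP:GQ genotype columns.
#' Genotypes masked to missing are written './.'. When the set was read
#' from a VCF, the original GT strings are reused (so multiallelic calls
#' round-trip); otherwise GT is reconstructed from the dosage.
#'
#' @param snps a [snp_set()].
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=divscan",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank-sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snps$samples), collapse = "\t"))
  writeLines(hdr, con)
  m <- nrow(snps$sites)
  if (m == 0) return(invisible(path))
  fmt1 <- function(key, x) ifelse(is.na(x), NA, paste0(key, "=", signif(x, 6)))
  info <- apply(cbind(fmt1("QD", snps$sites$qd), fmt1("FS", snps$sites$fs),
                      fmt1("MQ", snps$sites$mq),
                      fmt1("ReadPosRankSum", snps$sites$rprs)),
                1, function(r) {
                  r <- r[!is.na(r)]
                  if (!length(r)) "." else paste(r, collapse = ";")
                })
  gt_chr <- if (!is.null(snps$gt_str)) {
    gs <- snps$gt_str
    gs[is.na(snps$gt)] <- "./."
    gs[is.na(gs)] <- "./."
    gs
  } else {
    matrix(dosage_to_gt(snps$gt), nrow = m, dimnames = dimnames(snps$gt))
  }
  num_chr <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  cols <- vapply(seq_along(snps$samples), function(j) {
    paste(gt_chr[, j], num_chr(snps$dp[, j]), num_chr(snps$gq[, j]),
          sep = ":")
  }, character(m))
  if (m == 1) cols <- matrix(cols, nrow = 1)
  body <- paste(snps$sites$scaffold, snps$sites$pos, ".", snps$sites$ref,
                snps$sites$alt, ".", ".", info, "GT:DP:GQ",
                apply(cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
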