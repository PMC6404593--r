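# Independent oracles: every routine here recomputes a statistic by a
# different route than the package (direct pairwise counting, explicit
# enumeration, closed forms) and is kept free of package internals.

# Average pairwise difference sum for a set of sites, counted directly
# over all pairs of called alleles (chromosomes) at each site.
oracle_pi_sum <- function(gt) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  total <- 0
  for (i in seq_len(nrow(gt))) {
    g <- unname(gt[i, ])
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    # expand dosages to allele vectors
    alleles <- unlist(lapply(g, function(d) switch(d + 1L, c(0L, 0L),
                                                   c(0L, 1L), c(1L, 1L))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1))
      for (b in (a + 1):n) diffs <- diffs + (alleles[a] != alleles[b])
    total <- total + diffs / choose(n, 2)
  }
  total
}

# Tajima's D by direct evaluation of the classical formula, with the
# pairwise-difference part counted explicitly (complete matrices only).
oracle_tajima_d <- function(gt) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  stopifnot(!anyNA(gt))
  n <- 2 * ncol(gt)
  j <- rowSums(gt)
  S <- sum(j > 0 & j < n)
  if (S == 0) return(NA_real_)
  khat <- oracle_pi_sum(gt)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exact HWE p-value by full enumeration of heterozygote counts with
# log-factorial probabilities (no recurrence).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  R <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  if (R == 0) return(1.0)
  hets <- seq.int(R %% 2, R, by = 2)
  lp <- vapply(hets, function(h) {
    hr <- (R - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Upper-tail hypergeometric probability by direct summation of
# binomial-coefficient terms.
oracle_fisher <- function(k, q, t, U) {
  xs <- k:min(q, t)
  if (k > min(q, t)) return(0)
  sum(exp(lchoose(t, xs) + lchoose(U - t, q - xs) - lchoose(U, q)))
}

# Step-up BH adjustment written out by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Partition-function motif score by memoised suffix recursion in raw
# probability space (the package works front-to-back on probability
# ratios in C++): f(i) sums, over all placements in the suffix starting
# at i, background emissions times (t/2)-weighted PWM emissions.
oracle_stubb <- function(seq, mat, bg, t) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  w <- ncol(mat)
  code <- match(s, c("A", "C", "G", "T"))
  memo <- rep(NA_real_, L + 1)
  pw <- function(pos, strand) {
    idx <- code[pos:(pos + w - 1)]
    if (strand == "+") prod(mat[cbind(idx, seq_len(w))])
    else prod(mat[cbind(5 - rev(idx), seq_len(w))])
  }
  rec <- function(i) {
    if (i > L) return(1)
    if (!is.na(memo[i])) return(memo[i])
    val <- (1 - t) * bg[code[i]] * rec(i + 1)
    if (i + w - 1 <= L)
      val <- val + (t / 2) * (pw(i, "+") + pw(i, "-")) * rec(i + w)
    memo[i] <<- val
    val
  }
  unname(log(rec(1)) - sum(log(bg[code])))
}

# Brute-force evaluation of the whole filter cascade, one record at a
# time, straight from the predicate definitions.
oracle_cascade_keep <- function(snps, cfg) {
  s <- snps$sites
  cohort <- setdiff(snps$samples, cfg$haploid_sample)
  keep <- logical(nrow(s))
  for (i in seq_len(nrow(s))) {
    ok <- (is.na(s$qd[i]) || s$qd[i] >= cfg$qd_min) &&
      (is.na(s$fs[i]) || s$fs[i] <= cfg$fs_max) &&
      (is.na(s$mq[i]) || s$mq[i] >= cfg$mq_min) &&
      (is.na(s$rprs[i]) || s$rprs[i] >= cfg$rprs_min) &&
      (!cfg$biallelic_only || s$n_alt[i] == 1)
    if (ok && !is.null(cfg$haploid_sample)) {
      g <- snps$gt[i, cfg$haploid_sample]
      if (!is.na(g) && g == 1) ok <- FALSE
    }
    if (ok) {
      g <- snps$gt[i, cohort]
      d <- snps$dp[i, cohort]
      q <- snps$gq[i, cohort]
      if (cfg$dp_min > 0 || cfg$gq_min > 0)
        g[is.na(d) | d < cfg$dp_min | is.na(q) | q < cfg$gq_min] <- NA
      called <- !is.na(g)
      if (!any(called)) ok <- FALSE
      else {
        f <- sum(g[called]) / (2 * sum(called))
        ok <- mean(d[called]) >= cfg$min_mean_dp &&
          sum(!called) <= cfg$max_missing_count &&
          min(f, 1 - f) >= cfg$maf_min
      }
    }
    keep[i] <- ok
  }
  keep
}

# Small random snp_set generator for property tests.
random_snp_set <- function(m = 200, n_dip = 6, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("S%02d", seq_len(n_dip)), "HAP")
  nS <- length(samples)
  sites <- data.frame(
    scaffold = "s1", pos = sort(sample.int(1e6, m)),
    ref = "A", alt = ifelse(runif(m) < 0.1, "C,G", "C"),
    qd = ifelse(runif(m) < 0.15, NA, runif(m, 0, 40)),
    fs = ifelse(runif(m) < 0.15, NA, runif(m, 0, 100)),
    mq = ifelse(runif(m) < 0.15, NA, runif(m, 20, 60)),
    rprs = ifelse(runif(m) < 0.15, NA, runif(m, -15, 5)),
    stringsAsFactors = FALSE)
  sites$n_alt <- ifelse(grepl(",", sites$alt), 2L, 1L)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), m * nS, replace = TRUE,
                      prob = c(0.45, 0.25, 0.2, 0.1)), m,
               dimnames = list(NULL, samples))
  dp <- matrix(rpois(m * nS, 8), m, dimnames = list(NULL, samples))
  gq <- matrix(sample(0:99, m * nS, replace = TRUE), m,
               dimnames = list(NULL, samples))
  snp_set(sites, gt, dp, gq, samples, haploid = "HAP")
}
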