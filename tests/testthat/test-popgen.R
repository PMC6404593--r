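test_that("site_pi evaluates the pairwise-difference formula", {
  expect_equal(site_pi(4, 2), 2 * 2 * 2 / (4 * 3))
  expect_equal(site_pi(36, 0), 0)
  expect_equal(site_pi(2, 1), 1.0)
  expect_true(is.na(site_pi(1, 0)))     # undefined, distinct from 0
  expect_error(site_pi(4, 5), "alt_count")
  # bound n/(2(n-1)), attained only at j = n/2
  for (n in c(4, 10, 36)) {
    j <- 0:n
    v <- site_pi(rep(n, n + 1), j)
    expect_true(all(v <= n / (2 * (n - 1)) + 1e-12))
    expect_equal(which(v == max(v)) - 1, n / 2)
  }
})

test_that("Tajima constants match closed forms and direct sums", {
  c2 <- tajima_constants(2)
  expect_equal(c2[["a1"]], 1)
  expect_equal(c2[["a2"]], 1)
  expect_equal(c2[["b1"]], 1)
  c10 <- tajima_constants(10)
  expect_equal(c10[["a1"]], sum(1 / 1:9), tolerance = 1e-12)
  expect_equal(c10[["a2"]], sum(1 / (1:9)^2), tolerance = 1e-12)
  # n = 2 and n = 3 are degenerate: c1 = b1 - 1/a1 = 0 exactly (and c2
  # likewise), so e1 = e2 = 0 and D is 0/0 there; both are strictly
  # positive from n = 4
  expect_equal(c2[["e1"]], 0)
  expect_equal(c2[["e2"]], 0)
  expect_equal(tajima_constants(3)[["e1"]], 0)
  for (n in 4:100) {
    cn <- tajima_constants(n)
    expect_gt(cn[["e1"]], 0)
    expect_gt(cn[["e2"]], 0)
  }
  expect_error(tajima_constants(1), "at least 2")
})

test_that("window Tajima's D matches the direct-formula oracle", {
  # 4 chromosomes, 3 segregating sites, all singletons
  gt <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L))
  expect_equal(window_tajimas_d(gt), oracle_tajima_d(gt),
               tolerance = 1e-9)
  # random complete windows over a range of shapes
  set.seed(42)
  for (rep in 1:20) {
    ns <- sample(2:10, 1)
    m <- sample(1:15, 1)
    g <- matrix(sample(0:2, m * ns, replace = TRUE), m, ns)
    expect_equal(window_tajimas_d(g), oracle_tajima_d(g),
                 tolerance = 1e-9)
  }
})

test_that("D is undefined (not zero) when no site segregates", {
  gt <- rbind(c(0L, 0L), c(2L, 2L))
  expect_true(is.na(window_tajimas_d(gt)))
  expect_true(is.na(window_tajimas_d(matrix(integer(0), 0, 2))))
})

test_that("D is invariant to swapping ref and alt at every site", {
  set.seed(7)
  g <- matrix(sample(0:2, 60, replace = TRUE), 12, 5)
  expect_equal(window_tajimas_d(g), window_tajimas_d(2L - g),
               tolerance = 1e-12)
})

test_that("windowed pi uses the stated denominators", {
  # one site with site_pi = 0.5 in a 1 kb window
  samples <- c("A", "B")
  sites <- data.frame(scaffold = "s1", pos = 500L, ref = "A", alt = "C",
                      qd = 30, fs = 0, mq = 60, rprs = 0, n_alt = 1L)
  gt <- matrix(c(1L, 0L), 1, 2, dimnames = list(NULL, samples))
  dp <- gq <- matrix(30L, 1, 2, dimnames = list(NULL, samples))
  snps <- snp_set(sites, gt, dp, gq, samples)
  lens <- c(s1 = 1000L)
  win <- windowed_diversity(snps, lens, window = 1000L)
  expect_equal(win$pi, site_pi(4, 1) / 1000)
  # corrected: 500 of 1000 sites covered -> denominator 500
  cov <- data.frame(scaffold = "s1", start = 0L, end = 1000L,
                    fraction = 0.5)
  win2 <- windowed_diversity(snps, lens, window = 1000L, coverage = cov)
  expect_equal(win2$pi_corrected, site_pi(4, 1) / 500)
  expect_equal(win2$pi_corrected, 2 * win2$pi)
  # full coverage: corrected equals uncorrected
  cov$fraction <- 1
  win3 <- windowed_diversity(snps, lens, window = 1000L, coverage = cov)
  expect_equal(win3$pi_corrected, win3$pi)
  # a window with no covered sites has undefined corrected pi
  cov$fraction <- 0
  win4 <- windowed_diversity(snps, lens, window = 1000L, coverage = cov)
  expect_true(is.na(win4$pi_corrected))
})

test_that("window pi sums agree with direct pairwise-difference counting", {
  set.seed(19)
  for (rep in 1:5) {
    nsamp <- sample(c(5, 20, 50), 1)
    m <- 40
    samples <- sprintf("S%02d", seq_len(nsamp))
    gt <- matrix(sample(c(0L, 1L, 2L, NA), m * nsamp, replace = TRUE,
                        prob = c(0.4, 0.3, 0.2, 0.1)), m,
                 dimnames = list(NULL, samples))
    sites <- data.frame(scaffold = "s1", pos = sort(sample.int(3000, m)),
                        ref = "A", alt = "C", qd = 30, fs = 0, mq = 60,
                        rprs = 0, n_alt = 1L)
    snps <- snp_set(sites, gt, matrix(30L, m, nsamp),
                    matrix(99L, m, nsamp), samples)
    win <- windowed_diversity(snps, c(s1 = 3000L), window = 1000L)
    for (k in seq_len(nrow(win))) {
      rows <- sites$pos > win$start[k] & sites$pos <= win$end[k]
      expect_equal(win$pi[k] * 1000,
                   oracle_pi_sum(gt[rows, , drop = FALSE]),
                   tolerance = 1e-9)
    }
  }
})

test_that("heterozygosity F has the expected sign and null behaviour", {
  set.seed(5)
  m <- 4000
  p <- runif(m, 0.1, 0.9)
  # cohort of 10 HWE samples
  gt <- vapply(1:10, function(i) rbinom(m, 2, p), numeric(m))
  colnames(gt) <- sprintf("S%02d", 1:10)
  hw <- individual_heterozygosity(gt)
  expect_true(all(abs(hw$F) < 0.05))
  expect_true(all(hw$observed_hom >= 0 & hw$observed_hom <= hw$n_sites))
  # an all-heterozygous sample has negative F, an all-homozygous positive
  gt2 <- gt
  gt2[, 1] <- 1L
  gt2[, 2] <- 2L * rbinom(m, 1, p)
  hw2 <- individual_heterozygosity(gt2)
  expect_lt(hw2$F[1], 0)
  expect_gt(hw2$F[2], 0)
})

test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(5, 0, 5), oracle_hwe(5, 0, 5),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(1:60, 1)
    aa <- sample(0:n, 1)
    ab <- sample(0:(n - aa), 1)
    bb <- n - aa - ab
    p <- hwe_exact_test(aa, ab, bb)
    expect_equal(p, oracle_hwe(aa, ab, bb), tolerance = 1e-12)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("Ajk relatedness separates duplicates from unrelated pairs", {
  set.seed(3)
  m <- 12000
  p <- runif(m, 0.05, 0.95)
  gt <- vapply(1:20, function(i) rbinom(m, 2, p), numeric(m))
  colnames(gt) <- sprintf("S%02d", 1:20)
  gt[, 20] <- gt[, 1]                       # duplicated individual
  rel <- relatedness_ajk(gt)
  expect_true(isSymmetric(rel$ajk))
  # the duplicate pair stands far above every unrelated pair
  off <- rel$ajk[1:19, 1:19][lower.tri(matrix(0, 19, 19))]
  expect_gt(rel$ajk[1, 20], max(off) + 0.5)
  expect_lt(max(abs(off)), 0.3)
  expect_error(relatedness_ajk(rbind(c(0L, 0L), c(2L, 2L))),
               "polymorphic")
})

test_that("Ajk is calibrated on a large unrelated cohort", {
  set.seed(8)
  m <- 10000
  p <- runif(m, 0.05, 0.95)
  gt <- vapply(1:100, function(i) rbinom(m, 2, p), numeric(m))
  colnames(gt) <- sprintf("S%03d", 1:100)
  gt[, 100] <- gt[, 1]                      # one duplicated individual
  rel <- relatedness_ajk(gt)
  expect_gt(rel$ajk[1, 100], 0.9)
  off <- rel$ajk[1:99, 1:99][lower.tri(matrix(0, 99, 99))]
  expect_lt(abs(mean(off)), 0.05)
  expect_gt(rel$n_sites_used, 9000)
})
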