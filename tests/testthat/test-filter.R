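test_that("site hard filters apply strict-inequality GATK semantics", {
  fx <- filter_demo_records()
  cfg <- filter_config(haploid_sample = "M01")
  res <- apply_site_hard_filters(fx$snps, cfg)
  pos_kept <- res$snps$sites$pos
  # QD 1.5 / FS 70 / MQ 35 / RPRS -9 / triallelic / double failure removed
  expect_false(any(c(1000, 2000, 3000, 4000, 5000, 6000) %in% pos_kept))
  # exact-threshold records survive: QD 2.0, FS 60.0, MQ 40.0, RPRS -8.0
  expect_true(all(c(12000, 16000, 17000, 18000) %in% pos_kept))
  expect_equal(res$report$stages$n_removed, 6)
})

test_that("a missing INFO annotation passes its predicate and is counted", {
  fx <- filter_demo_records()
  fx$snps$sites$qd[19] <- NA  # r19 otherwise clean
  res <- apply_site_hard_filters(fx$snps, filter_config())
  expect_true(19000 %in% res$snps$sites$pos)
  rs <- res$report$reasons
  expect_equal(rs$count[rs$reason == "missing_info"], 1)
})

test_that("haploid-consistency removes heterozygous male calls only", {
  fx <- filter_demo_records()
  res <- apply_haploid_consistency(fx$snps, "M01")
  expect_equal(res$report$stages$n_removed, 2)
  expect_false(any(c(7000, 8000) %in% res$snps$sites$pos))
  # missing haploid genotype (r20) is retained and counted
  expect_true(20000 %in% res$snps$sites$pos)
  rs <- res$report$reasons
  expect_equal(rs$count[rs$reason == "haploid_missing"], 1)
  expect_error(apply_haploid_consistency(fx$snps, "NOBODY"), "unknown")
})

test_that("genotype masking respects DP/GQ boundaries", {
  samples <- c("A", "B", "HAP")
  sites <- data.frame(scaffold = "s", pos = 1:2, ref = "A", alt = "C",
                      qd = 30, fs = 1, mq = 55, rprs = 0, n_alt = 1L)
  gt <- matrix(1L, 2, 3, dimnames = list(NULL, samples))
  dp <- matrix(c(2, 3, 30, 30, 30, 30), 2, byrow = FALSE)
  gq <- matrix(c(99, 99, 9, 8, 99, 99), 2, byrow = FALSE)
  snps <- snp_set(sites, gt, dp, gq, samples, haploid = "HAP")
  out <- apply_genotype_filters(snps, filter_config())$snps
  expect_true(is.na(out$gt[1, 1]))     # DP 2 < 3 masked
  expect_false(is.na(out$gt[2, 1]))    # DP 3 retained (strict <)
  expect_false(is.na(out$gt[1, 2]))    # GQ 9 retained
  expect_true(is.na(out$gt[2, 2]))     # GQ 8 masked
  # sites survive this stage even if fully masked
  expect_equal(nrow(out$sites), 2)
})

test_that("cohort filters implement meanDP / missingness / MAF rules", {
  fx <- filter_demo_records()
  cfg <- filter_config(haploid_sample = "M01")
  pre <- apply_genotype_filters(
    apply_haploid_consistency(
      apply_site_hard_filters(fx$snps, cfg)$snps, "M01")$snps, cfg)
  res <- apply_cohort_filters(pre$snps, cfg)
  expect_equal(res$report$stages$n_removed, 3)
  pos <- res$snps$sites$pos
  expect_false(any(c(9000, 10000, 11000) %in% pos))
  expect_true(13000 %in% pos)  # mean DP exactly 5 survives
  expect_true(14000 %in% pos)  # exactly 4 missing survives
  expect_true(15000 %in% pos)  # MAF 2/36 survives
})

test_that("the cascade matches its hand evaluation and is idempotent", {
  fx <- filter_demo_records()
  cfg <- filter_config(haploid_sample = "M01")
  res <- run_filter_cascade(fx$snps, cfg)
  expect_equal(n_sites(res$snps), fx$expected$survivors)
  expect_equal(res$snps$sites$pos, fx$expected$surviving_pos)
  expect_equal(res$report$stages[, c("stage", "n_in", "n_removed", "n_out")],
               fx$expected$stages)
  again <- run_filter_cascade(res$snps, cfg)
  expect_equal(again$snps$sites, res$snps$sites)
  expect_equal(again$snps$gt, res$snps$gt)
  expect_equal(sum(again$report$stages$n_removed), 0)
})

test_that("the cascade works identically through VCF files", {
  fx <- filter_demo_records()
  cfg <- filter_config(haploid_sample = "M01")
  vin <- tempfile(fileext = ".vcf")
  vout <- tempfile(fileext = ".vcf")
  rout <- tempfile(fileext = ".tsv")
  write_vcf(fx$snps, vin)
  res <- run_filter_cascade(vin, cfg, out = vout, report = rout)
  expect_equal(n_sites(res$snps), 9)
  back <- read_vcf(vout, haploid = "M01")
  expect_equal(back$sites$pos, fx$expected$surviving_pos)
  rep_tsv <- read.table(rout, header = TRUE, sep = "\t")
  expect_equal(rep_tsv$n_out[4], 9)
})

test_that("an empty VCF passes through with a zero-count report", {
  samples <- c("A", "B", "HAP")
  empty <- snp_set(data.frame(scaffold = character(), pos = integer(),
                              ref = character(), alt = character(),
                              qd = numeric(), fs = numeric(),
                              mq = numeric(), rprs = numeric(),
                              n_alt = integer()),
                   matrix(integer(0), 0, 3), matrix(integer(0), 0, 3),
                   matrix(integer(0), 0, 3), samples, haploid = "HAP")
  path <- tempfile(fileext = ".vcf")
  write_vcf(empty, path)
  res <- run_filter_cascade(path, filter_config(haploid_sample = "HAP"))
  expect_equal(n_sites(res$snps), 0)
  expect_true(all(res$report$stages$n_removed == 0))
})

test_that("counts conserve at every stage of the cascade", {
  for (seed in 1:3) {
    snps <- random_snp_set(seed = seed)
    res <- run_filter_cascade(snps, filter_config(haploid_sample = "HAP",
                                                  max_missing_count = 2))
    st <- res$report$stages
    expect_equal(st$n_in - st$n_removed, st$n_out)
    expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
  }
})

test_that("the cascade equals a brute-force per-record evaluator", {
  for (seed in 1:5) {
    snps <- random_snp_set(m = 200, seed = seed)
    cfg <- filter_config(haploid_sample = "HAP",
                         max_missing_count = sample(0:4, 1),
                         maf_min = runif(1, 0, 0.3),
                         min_mean_dp = runif(1, 0, 10))
    res <- run_filter_cascade(snps, cfg)
    keep <- oracle_cascade_keep(snps, cfg)
    expect_equal(res$snps$sites$pos, snps$sites$pos[keep])
  }
})

test_that("relaxing any single threshold never decreases survivors", {
  snps <- random_snp_set(m = 300, seed = 11)
  base <- filter_config(haploid_sample = "HAP")
  n0 <- n_sites(run_filter_cascade(snps, base)$snps)
  relax <- list(qd_min = 0, fs_max = 1e6, mq_min = 0, rprs_min = -1e6,
                min_mean_dp = 0, max_missing_count = 7, maf_min = 0,
                gq_min = 0, dp_min = 0)
  for (nm in names(relax)) {
    cfg <- base
    cfg[[nm]] <- relax[[nm]]
    expect_gte(n_sites(run_filter_cascade(snps, cfg)$snps), n0)
  }
})

test_that("filter presets reproduce the two calling rounds", {
  p1 <- filter_preset("round1")
  expect_equal(p1$max_missing_count, 0)
  expect_equal(p1$maf_min, 0)
  p2 <- filter_preset("round2_gatk")
  expect_equal(p2$max_missing_count, 8)
  p3 <- filter_preset("round2_final")
  expect_equal(p3$maf_min, 0.05)
  expect_equal(p3$min_mean_dp, 5)
})
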