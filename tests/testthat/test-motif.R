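uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("window partition tiles with 250 bp steps and handles masks", {
  g <- Biostrings::DNAStringSet(c(
    s1 = paste(rep("ACGT", 250), collapse = ""),   # 1000 bp
    s2 = paste(rep("A", 300), collapse = "")))     # shorter than window
  part <- partition_windows(g)
  w1 <- part$windows[part$windows$scaffold == "s1", ]
  expect_equal(w1$start, c(0, 250, 500))
  expect_equal(w1$gc, rep(0.5, 3))
  w2 <- part$windows[part$windows$scaffold == "s2", ]
  expect_equal(nrow(w2), 1)
  expect_true(w2$partial)
  # a fully masked window is excluded from scoring
  mask <- data.frame(scaffold = "s1", start = 0L, end = 600L)
  pm <- partition_windows(g, mask = mask)
  wm <- pm$windows[pm$windows$scaffold == "s1", ]
  expect_false(wm$scored[1])
  expect_equal(wm$masked_fraction[1], 1)
})

test_that("background estimation uses long non-genic regions with a floor", {
  set.seed(2)
  g <- Biostrings::DNAStringSet(c(s1 = paste(
    sample(c("A", "C", "G", "T"), 30000, replace = TRUE), collapse = "")))
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 12000L,
                      end = 14000L, strand = "+", tss = 12000L)
  bg <- estimate_background(g, genes)
  expect_equal(sum(bg), 1)
  expect_true(all(bg > 0.23 & bg < 0.27))
  # all-A non-coding genome: floors keep every base > 0
  gA <- Biostrings::DNAStringSet(c(s1 = paste(rep("A", 30000),
                                              collapse = "")))
  bgA <- estimate_background(gA, genes)
  expect_equal(sum(bgA), 1)
  expect_true(all(bgA >= 0.001 / 1.003 - 1e-12))
  expect_gt(bgA[["A"]], 0.99)
  # short scaffolds fall back to whole-genome frequencies with a warning
  gshort <- Biostrings::DNAStringSet(c(s1 = paste(rep("ACGT", 500),
                                                  collapse = "")))
  expect_warning(bgs <- estimate_background(gshort, genes), "whole-genome")
  expect_equal(sum(bgs), 1)
})

test_that("the HMM window score has its limit and dominance properties", {
  pwm <- make_pwm("m1", "ACGTAC")
  set.seed(4)
  seqs <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  expect_equal(stubb_score_window(seqs, pwm, uniform_bg, t = 0), 0)
  with_site <- paste0(substr(seqs, 1, 20), "ACGTAC", substr(seqs, 27, 60))
  expect_gt(stubb_score_window(with_site, pwm, uniform_bg),
            stubb_score_window(seqs, pwm, uniform_bg))
  # too-short window is undefined
  expect_true(is.na(stubb_score_window("ACG", pwm, uniform_bg)))
})

test_that("the HMM score equals the placement-enumeration oracle", {
  set.seed(21)
  for (rep in 1:15) {
    w <- sample(3:5, 1)
    L <- sample(8:30, 1)
    pwm <- make_pwm(sprintf("m%d", rep),
                    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                          collapse = ""),
                    dominance = runif(1, 0.4, 1))
    bg <- runif(4, 0.5, 1.5)
    bg <- setNames(bg / sum(bg), c("A", "C", "G", "T"))
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    t <- sample(c(0.0025, 0.05, 0.3), 1)
    expect_equal(stubb_score_window(s, pwm, bg, t),
                 oracle_stubb(s, pwm$mat, bg, t), tolerance = 1e-9)
  }
})

test_that("rank normalization maps descending scores to [0, 1]", {
  expect_equal(rank_normalize(c(5, 3, 1)), c(0, 0.5, 1))
  expect_equal(rank_normalize(c(5, 5, 1)), c(0.25, 0.25, 1))
  expect_equal(rank_normalize(c(2, 7)), c(1, 0))
  expect_warning(out <- rank_normalize(c(3, 3, 3)), "identical")
  expect_equal(out, rep(0.5, 3))
  set.seed(6)
  x <- rnorm(100)
  rn <- rank_normalize(x)
  expect_equal(range(rn), c(0, 1))
  expect_equal(rn[which.max(x)], 0)
  # permutation equivariance
  perm <- sample(100)
  expect_equal(rank_normalize(x[perm]), rn[perm])
})

test_that("GC-binned rank normalization uses equal-count bins", {
  set.seed(12)
  gc40 <- runif(40)
  sc40 <- rnorm(40)
  gn <- gc_rank_normalize(sc40, gc40, bins = 20)
  expect_true(all(sort(unique(gn)) == c(0, 1)))  # bins of 2 -> {0,1}
  # 41 windows: first bin absorbs the remainder (size 3)
  gc41 <- c(gc40, 2)                             # unique largest GC
  sc41 <- c(sc40, 0)
  gn41 <- gc_rank_normalize(sc41, gc41, bins = 20)
  expect_equal(sum(gn41 == 0.5), 1)              # only the size-3 bin has 0.5
  expect_warning(gc_rank_normalize(rnorm(10), runif(10)), "bins")
})

test_that("GC-binned normalization removes a pure GC confound", {
  set.seed(42)
  ng <- 1000; wpg <- 5
  gc <- runif(ng * wpg, 0.2, 0.8)
  score <- gc                            # score is a pure function of GC
  gene <- rep(seq_len(ng), each = wpg)
  sel_mean_gc <- function(norm) {
    ngm <- tapply(norm, gene, min)
    best <- vapply(seq_len(ng), function(g) {
      idx <- which(gene == g)
      idx[which.min(norm[idx])]
    }, integer(1))
    top <- order(ngm)[1:100]
    mean(gc[best[top]])
  }
  rank_set <- sel_mean_gc(rank_normalize(score))
  gc_set <- sel_mean_gc(gc_rank_normalize(score, gc))
  expect_gt(abs(rank_set - mean(gc)), 0.1)
  expect_lt(abs(gc_set - mean(gc)), 0.02)
})

test_that("regulatory regions follow strand-oriented definitions", {
  lens <- c(s1 = 50000L)
  genes <- data.frame(gene_id = c("gP", "gM"), scaffold = "s1",
                      start = c(10000L, 30000L), end = c(12000L, 32000L),
                      strand = c("+", "-"), tss = c(10000L, 32000L),
                      stringsAsFactors = FALSE)
  r1 <- regulatory_regions(genes, "1Kup", lens)
  expect_equal(r1$start[r1$gene_id == "gP"], 9000)
  expect_equal(r1$end[r1$gene_id == "gP"], 10000)
  expect_equal(r1$start[r1$gene_id == "gM"], 32000)
  expect_equal(r1$end[r1$gene_id == "gM"], 33000)
  r2 <- regulatory_regions(genes, "5Kup2Kdown", lens)
  expect_equal(r2$start[r2$gene_id == "gP"], 5000)
  expect_equal(r2$end[r2$gene_id == "gP"], 12000)
  expect_equal(r2$start[r2$gene_id == "gM"], 30000)
  expect_equal(r2$end[r2$gene_id == "gM"], 37000)
  # clipping at the scaffold edge
  edge <- genes
  edge$start[1] <- 2000L; edge$end[1] <- 4000L; edge$tss[1] <- 2000L
  r3 <- regulatory_regions(edge, "5Kup", lens)
  expect_equal(r3$start[r3$gene_id == "gP"], 0)
})

test_that("NearStartSite assigns windows by TSS bisector with ties shared", {
  lens <- c(s1 = 10000L)
  genes <- data.frame(gene_id = c("gA", "gB"), scaffold = "s1",
                      start = c(0L, 10000L), end = c(100L, 10000L),
                      strand = "+", tss = c(0L, 10000L),
                      stringsAsFactors = FALSE)
  win <- data.frame(scaffold = "s1", start = seq(0, 9500, 500),
                    end = seq(500, 10000, 500), stringsAsFactors = FALSE)
  rr <- regulatory_regions(genes, "NearStartSite", lens, windows = win)
  a <- rr[rr$gene_id == "gA", ]
  b <- rr[rr$gene_id == "gB", ]
  # midpoints run 250..9750; the bisector sits at 5000
  expect_true(all((a$start + a$end) / 2 <= 5000))
  expect_true(all((b$start + b$end) / 2 >= 5000))
  # the window with midpoint exactly 4750/5250 is unshared; none tie here
  expect_equal(nrow(a) + nrow(b), nrow(win))
})

test_that("GeneTerr spans neighbour boundaries with a 5 kb upstream floor", {
  lens <- c(s1 = 100000L)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), scaffold = "s1",
                      start = c(10000L, 20000L, 24000L),
                      end = c(12000L, 22000L, 26000L),
                      strand = c("+", "+", "-"),
                      tss = c(10000L, 20000L, 26000L),
                      stringsAsFactors = FALSE)
  rr <- regulatory_regions(genes, "GeneTerr", lens)
  # g2: neighbours end at 12000 (left) and start at 24000 (right);
  # 5 kb upstream of TSS 20000 reaches further left
  expect_equal(rr$start[rr$gene_id == "g2"], 12000)
  expect_equal(rr$end[rr$gene_id == "g2"], 24000)
  # g1: no left neighbour -> scaffold start
  expect_equal(rr$start[rr$gene_id == "g1"], 0)
  # g3 on minus strand extends at least 5 kb right of its TSS
  expect_gte(rr$end[rr$gene_id == "g3"], 31000)
})

test_that("Pgm combines the best window score with the window count", {
  win <- data.frame(scaffold = "s1", start = c(0, 250, 500),
                    end = c(500, 750, 1000), gc = 0.4,
                    masked_fraction = 0, partial = FALSE, scored = TRUE,
                    stringsAsFactors = FALSE)
  norm <- matrix(c(0.5, 0.9, 0.2), 3, 1,
                 dimnames = list(NULL, "m1"))
  regions <- data.frame(gene_id = c("gA", "gB"), scaffold = "s1",
                        start = c(0L, 600L), end = c(400L, 900L),
                        stringsAsFactors = FALSE)
  sc <- gene_motif_scores(regions, win, norm)
  # gA overlaps windows 1+2 (Wg = 2, Ngm = 0.5): Pgm = 1 - 0.25
  expect_equal(sc$Wg[["gA"]], 2)
  expect_equal(sc$pgm["gA", "m1"], 0.75)
  # gB overlaps windows 2+3 (Ngm = 0.2, Wg = 2)
  expect_equal(sc$pgm["gB", "m1"], 1 - 0.8^2)
  # identities: Wg = 1 passes Ngm through; Ngm = 0 absorbs
  norm0 <- matrix(c(0, 0.9, 0.3), 3, 1, dimnames = list(NULL, "m1"))
  sc0 <- gene_motif_scores(regions, win, norm0)
  expect_equal(sc0$pgm["gA", "m1"], 0)
})

test_that("Pgm is monotone in Ngm and in Wg", {
  ngm <- seq(0.05, 0.95, by = 0.1)
  p1 <- 1 - (1 - ngm)^3
  expect_true(all(diff(p1) > 0))
  for (n in ngm) {
    p_w <- 1 - (1 - n)^(1:6)
    expect_true(all(diff(p_w) > 0))
    expect_true(all(p_w >= 0 & p_w <= 1))
  }
})

test_that("target-set counts multiply out and truncate with a flag", {
  set.seed(33)
  fake_scores <- function(n_genes, motifs) {
    ids <- sprintf("g%03d", seq_len(n_genes))
    pgm <- matrix(runif(n_genes * length(motifs)), n_genes,
                  dimnames = list(ids, motifs))
    list(gene_id = ids, Wg = setNames(rep(3L, n_genes), ids),
         ngm = pgm, pgm = pgm)
  }
  sc <- list("rank.1Kup" = fake_scores(50, c("m1")),
             "gc.1Kup" = fake_scores(50, c("m1")),
             "rank.GeneTerr" = fake_scores(50, c("m1")),
             "gc.GeneTerr" = fake_scores(50, c("m1")))
  ts <- build_target_sets(sc)
  expect_equal(length(ts$sets), 8)           # 1 motif -> 8 sets
  expect_true(all(ts$manifest$n_genes == 50))
  expect_true(all(ts$manifest$truncated))    # 50 genes < both sizes
  # ordering is by Pgm then gene id
  one <- ts$sets[["m1.rank.1Kup.conservative"]]
  pg <- sc[["rank.1Kup"]]$pgm[one, "m1"]
  expect_true(all(diff(pg) >= 0))
})

test_that("motif matrices round-trip through MEME and TSV formats", {
  pwms <- list(make_pwm("mA", "ACGTACGT"), make_pwm("mB", "TTTTTTAA",
                                                    dominance = 0.8))
  meme <- tempfile(fileext = ".meme")
  write_pwms_meme(pwms, meme)
  back <- read_pwms_meme(meme)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$id, "mA")
  expect_equal(back[[2]]$mat, pwms[[2]]$mat, tolerance = 1e-5)
  expect_true(all(abs(colSums(back[[1]]$mat) - 1) < 1e-4))
  tsv <- tempfile(fileext = ".tsv")
  write_pwm_tsv(pwms[[1]], tsv)
  back1 <- read_pwm_tsv(tsv, id = "mA")
  expect_equal(back1$mat, pwms[[1]]$mat, tolerance = 1e-12)
  expect_equal(back1$consensus, "ACGTACGT")
})

test_that("planted consensus sites outscore background windows", {
  cfg <- sim_config(seed = 19, genome_length = 2e5, n_scaffolds = 1,
                    n_genes = 40, n_motifs = 2,
                    planted_gene_fraction = 0.25)
  g <- simulate_genome(cfg)
  genes <- simulate_gene_models(cfg, g)
  plant <- simulate_pwms_and_plant_sites(cfg, g, genes)
  expect_equal(nrow(plant$planted_sites), 10)
  # planted sites sit inside the 1 kb upstream region of their gene
  for (i in seq_len(nrow(plant$planted_sites))) {
    ps <- plant$planted_sites[i, ]
    gn <- genes[genes$gene_id == ps$gene_id, ]
    if (gn$strand == "+") {
      expect_gte(ps$position, gn$tss - 1000)
      expect_lte(ps$position + cfg$motif_length, gn$tss)
    } else {
      expect_gte(ps$position, gn$tss)
      expect_lte(ps$position + cfg$motif_length, gn$tss + 1000)
    }
  }
  # planted windows land above the 99th percentile of background scores
  part <- partition_windows(plant$genome)
  bg <- estimate_background(plant$genome, genes)
  raw <- score_motif_windows(part, plant$pwms[1], bg)
  sw <- part$windows[part$windows$scored, ]
  hit <- vapply(seq_len(nrow(sw)), function(i) {
    any(plant$planted_sites$scaffold == sw$scaffold[i] &
          plant$planted_sites$position >= sw$start[i] &
          plant$planted_sites$position < sw$end[i])
  }, logical(1))
  expect_gt(min(raw[hit, 1]), quantile(raw[!hit, 1], 0.99))
  # planted_gene_fraction = 0 leaves the genome untouched
  cfg0 <- sim_config(seed = 19, genome_length = 2e5, n_scaffolds = 1,
                     n_genes = 40, planted_gene_fraction = 0)
  plant0 <- simulate_pwms_and_plant_sites(cfg0, g, genes)
  expect_identical(as.character(plant0$genome), as.character(g))
  expect_equal(nrow(plant0$planted_sites), 0)
})
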