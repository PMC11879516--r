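# Clumping + thresholding polygenic scores.

test_that("ld_r2 equals the squared Pearson correlation", {
  D <- cbind(a = c(0, 1, 2, 0), b = c(2, 1, 0, 2), c = c(1, 1, 1, 1))
  g <- toy_geno(D)
  expect_equal(ld_r2(g, "a", "a"), 1.0)
  expect_equal(ld_r2(g, "a", "b"), 1.0)     # perfect anticorrelation squares to 1
  expect_warning(r <- ld_r2(g, "a", "c"), "monomorphic")
  expect_equal(r, 0)
  # 6-subject pair against the direct formula
  set.seed(2)
  D6 <- cbind(x = sample(0:2, 6, TRUE), y = sample(0:2, 6, TRUE))
  while (sd(D6[, 1]) == 0 || sd(D6[, 2]) == 0)
    D6 <- cbind(x = sample(0:2, 6, TRUE), y = sample(0:2, 6, TRUE))
  g6 <- toy_geno(D6)
  x <- D6[, 1]; y <- D6[, 2]
  manual <- (sum((x - mean(x)) * (y - mean(y))) /
               sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(ld_r2(g6, "x", "y"), manual, tolerance = 1e-12)
})

test_that("clumping keeps the most significant SNP per LD neighbourhood", {
  # single SNP
  D <- matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(NULL, "only"))
  g <- toy_geno(D)
  ss <- data.frame(snp = "only", chr = "1", bp = 1000L, p = 0.5)
  expect_equal(clump(ss, g), "only")
  # two SNPs 500 kb apart in perfect LD: smaller p wins
  D2 <- cbind(s1 = c(0, 1, 2, 0, 1), s2 = c(0, 1, 2, 0, 1))
  g2 <- toy_geno(D2, bp = c(100000L, 600000L))
  ss2 <- data.frame(snp = c("s1", "s2"), chr = "1",
                    bp = c(100000L, 600000L), p = c(1e-4, 1e-8))
  expect_equal(clump(ss2, g2), "s2")
  expect_equal(clump(ss2[2:1, ], g2), "s2")   # row order irrelevant
  # empty input
  expect_equal(clump(ss2[0, ], g2), character(0))
})

test_that("clumping matches the independent greedy oracle on random instances", {
  for (case in 1:20) {
    set.seed(3000 + case)
    n_blocks <- 5; m <- 10
    cfg <- synth_config(seed = 3000 + case, n_subjects = 80,
                        n_blocks = n_blocks, snps_per_block = m,
                        block_corr = runif(1, 0.3, 0.95))
    g <- simulate_genotypes(cfg)
    ss <- simulate_summary_stats(g$map, cfg)
    got <- clump(ss, g)
    want <- oracle_clump(ss, g)
    expect_identical(got, want)
    # permutation invariance of the input rows
    perm <- sample(nrow(ss))
    expect_identical(clump(ss[perm, ], g), want)
  }
})

test_that("scores are dosage-weighted effect sums with allele alignment", {
  # one SNP, beta 0.5, dosages 0/1/2
  D <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "s1"))
  g <- toy_geno(D)
  ss <- data.frame(snp = "s1", chr = "1", bp = 1000L, a1 = "A", a2 = "G",
                   beta = 0.5, p = 1e-4)
  prof <- prs_score(g, ss, "s1", thresholds = 0.05)
  expect_equal(prof$score_0.05, c(0, 0.5, 1.0))
  # all betas zero -> all scores zero
  ss0 <- transform(ss, beta = 0)
  expect_true(all(prs_score(g, ss0, "s1", thresholds = 0.05)$score_0.05 == 0))
  # 3 SNPs x 4 subjects with one allele flip, against hand-computed sums
  D3 <- cbind(x = c(0, 1, 2, 2), y = c(2, 2, 0, 1), z = c(1, 0, 1, 2))
  g3 <- toy_geno(D3, a1 = c("A", "C", "T"), a2 = c("G", "T", "G"))
  ss3 <- data.frame(snp = c("x", "y", "z"), chr = "1", bp = 1:3 * 1000L,
                    a1 = c("A", "T", "T"), a2 = c("G", "C", "G"),
                    beta = c(0.2, -0.4, 0.1), p = c(1e-5, 1e-4, 1e-3))
  prof3 <- prs_score(g3, ss3, c("x", "y", "z"), thresholds = 0.01)
  # y is coded on the other allele in the genotype file: dosage flips to 2-d
  hand <- 0.2 * D3[, "x"] + (-0.4) * (2 - D3[, "y"]) + 0.1 * D3[, "z"]
  expect_equal(prof3$score_0.01, unname(hand), tolerance = 1e-12)
})

test_that("alleles matching neither orientation are dropped with a warning", {
  D <- cbind(ok = c(0, 1, 2), bad = c(1, 2, 0))
  g <- toy_geno(D, a1 = c("A", "A"), a2 = c("G", "G"))
  ss <- data.frame(snp = c("ok", "bad"), chr = "1", bp = c(1000L, 2000L),
                   a1 = c("A", "C"), a2 = c("G", "T"),
                   beta = c(1, 1), p = c(1e-4, 1e-4))
  expect_warning(prof <- prs_score(g, ss, c("ok", "bad"), thresholds = 0.05),
                 "dropped")
  expect_equal(prof$score_0.05, c(0, 1, 2))
  expect_equal(attr(prof, "n_dropped"), 1L)
})

test_that("threshold sets are nested and scores accumulate monotonically", {
  cfg <- synth_config(seed = 77, n_subjects = 120)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(g$map, cfg)
  kept <- clump(ss, g)
  prof <- prs_score(g, ss, kept)
  nu <- attr(prof, "n_snps_used")
  expect_true(all(diff(nu) >= 0))
  rl <- attr(prof, "retained_snps")
  for (i in seq_len(length(rl) - 1))
    expect_true(all(rl[[i]] %in% rl[[i + 1]]))
})

test_that("flipping a SNP's coded allele leaves score differences intact", {
  set.seed(11)
  D <- matrix(sample(0:2, 40, TRUE), 10, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  g <- toy_geno(D, a1 = c("A", "C", "A", "T"), a2 = c("G", "T", "C", "G"))
  ss <- data.frame(snp = paste0("s", 1:4), chr = "1", bp = 1:4 * 100000L,
                   a1 = g$map$a1, a2 = g$map$a2,
                   beta = rnorm(4), p = rep(1e-4, 4))
  p1 <- prs_score(g, ss, ss$snp, thresholds = 0.05)$score_0.05
  # recode SNP 3 on its other allele in the genotype file
  D2 <- D; D2[, 3] <- 2 - D[, 3]
  g2 <- toy_geno(D2, a1 = c("A", "C", "C", "T"), a2 = c("G", "T", "A", "G"))
  p2 <- prs_score(g2, ss, ss$snp, thresholds = 0.05)$score_0.05
  expect_equal(diff(p1), diff(p2), tolerance = 1e-12)
})
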