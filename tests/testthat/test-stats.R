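test_that("size factors recover depth multiples by median-of-ratios", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), rep(1, 2) * unname(size_factors(m))[1])
  m2 <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  rownames(m2) <- paste0("f", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # single-feature matrix (4, 8) -> factors proportional to (1, 2)
  m1 <- matrix(c(4, 8), 1, 2, dimnames = list("f1", c("a", "b")))
  sf1 <- size_factors(m1)
  expect_equal(unname(sf1[2] / sf1[1]), 2)
  # degenerate: no feature nonzero everywhere
  m0 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_error(size_factors(m0), "pseudocount")
  expect_length(size_factors(m0, pseudocount = 1), 2L)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(40)
  m <- matrix(rnbinom(600, mu = 50, size = 5) + 1, nrow = 100,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

make_paired <- function(ratios_feature, n_pad = 30, base = 50) {
  # one feature with prescribed after/before ratios + stable padding features
  n <- length(ratios_feature)
  before <- matrix(base, nrow = n_pad + 1, ncol = n)
  after <- before
  before[1, ] <- base
  after[1, ] <- base * ratios_feature
  m <- cbind(before, after)
  rownames(m) <- c("target", paste0("pad", seq_len(n_pad)))
  colnames(m) <- c(paste0("b", seq_len(n)), paste0("a", seq_len(n)))
  list(m = m, design = data.frame(subject = paste0("subj", seq_len(n)),
                                  before = paste0("b", seq_len(n)),
                                  after = paste0("a", seq_len(n)),
                                  stringsAsFactors = FALSE))
}

test_that("the paired log-ratio test recovers fold changes and the t closed form", {
  # identical before/after -> log2fc 0, p 1
  p0 <- make_paired(c(1, 1, 1, 1))
  r0 <- paired_logratio_test(p0$m, p0$design, pseudocount = 0)
  expect_equal(r0$log2fc, rep(0, nrow(p0$m)))
  expect_equal(r0$p, rep(1, nrow(p0$m)))
  # exact 4-fold overexpression with pseudocount -> 0: log2fc = 2
  p4 <- make_paired(c(4, 4, 4, 4))
  r4 <- paired_logratio_test(p4$m, p4$design, pseudocount = 0)
  expect_equal(r4$log2fc[r4$feature == "target"], 2)
  # ratios (2,2,2,1/2): r_i = (1,1,1,-1), t = 1 / (1/2) = 2... closed form
  pr <- make_paired(c(2, 2, 2, 0.5))
  rr <- paired_logratio_test(pr$m, pr$design, pseudocount = 0)
  ri <- c(1, 1, 1, -1)
  tstat <- mean(ri) / (sd(ri) / sqrt(4))
  expect_equal(rr$p[rr$feature == "target"], 2 * pt(-abs(tstat), df = 3))
  expect_equal(rr$log2fc[rr$feature == "target"], 0.5)
  # fewer than 2 subjects is an error
  expect_error(paired_logratio_test(p4$m, p4$design[1, , drop = FALSE]),
               "2 subjects")
})

test_that("swapping before and after negates log2fc and preserves p", {
  set.seed(41)
  m <- matrix(rnbinom(200 * 8, mu = 40, size = 5), nrow = 200,
              dimnames = list(paste0("f", 1:200),
                              c(paste0("b", 1:4), paste0("a", 1:4))))
  d <- data.frame(subject = paste0("s", 1:4), before = paste0("b", 1:4),
                  after = paste0("a", 1:4), stringsAsFactors = FALSE)
  dsw <- data.frame(subject = d$subject, before = d$after, after = d$before,
                    stringsAsFactors = FALSE)
  r1 <- paired_logratio_test(m, d)
  r2 <- paired_logratio_test(m, dsw)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p, r2$p)
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("the Friedman statistic and p-values behave as derived", {
  # identical conditions: statistic 0, p 1
  v <- matrix(5, nrow = 3, ncol = 3)
  f <- friedman_test(v)
  expect_equal(f$statistic, 0)
  expect_equal(f$p, 1)
  # every subject ranks C3 > C2 > C1: rank sums (4, 8, 12), Q = 8, df 2
  v <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3), nrow = 4)
  f <- friedman_test(v)
  expect_equal(f$statistic, 8)
  expect_equal(f$df, 2)
  expect_equal(f$p, pchisq(8, 2, lower.tail = FALSE))
  # tie-free statistic agrees with the base R implementation
  set.seed(43)
  v <- matrix(rnorm(12), 4, 3)
  expect_equal(friedman_test(v)$statistic,
               unname(stats::friedman.test(v)$statistic))
})

test_that("exact Friedman enumeration matches the oracle and the asymptotic tail", {
  set.seed(44)
  for (i in 1:5) {
    v <- matrix(rnorm(12), 4, 3)
    ex <- friedman_test(v, exact = TRUE)
    or <- oracle_friedman_exact(v)
    expect_equal(ex$statistic, or$statistic)
    expect_equal(ex$p, or$p)
  }
  # in the rejection region (exact p <= 0.125) the chi-square approximation
  # is within 0.02 of the exact tail for n = 4, k = 3
  strong <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3), nrow = 4)
  jitter <- strong + matrix(runif(12, 0, 0.1), 4, 3)
  for (v in list(strong, jitter)) {
    ex <- friedman_test(v, exact = TRUE)
    as <- friedman_test(v)
    expect_lte(ex$p, 0.125)
    expect_lt(abs(ex$p - as$p), 0.02)
  }
})

test_that("permutation Spearman gives exact small-n p-values", {
  x <- 1:5
  r <- spearman_perm(x, c(2, 4, 6, 8, 10))
  expect_equal(r$rho, 1)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 120)   # only the two perfect orderings reach |rho|=1
  expect_equal(spearman_perm(x, rev(x))$rho, -1)
  expect_error(spearman_perm(x, rep(1, 5)), "constant")
  # sampled mode: add-one estimator, deterministic given seed
  set.seed(45)
  y <- rnorm(9)
  x9 <- rnorm(9)
  r1 <- spearman_perm(x9, y, n_perm = 500, seed = 7)
  r2 <- spearman_perm(x9, y, n_perm = 500, seed = 7)
  expect_identical(r1, r2)
  expect_gt(r1$p, 0)
})

test_that("PCA scores have the declared variance and sign conventions", {
  set.seed(46)
  m <- matrix(rnbinom(50 * 4, mu = 60, size = 5) + 1, nrow = 50,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))
  # duplicated sample: distance 0 between its score vectors
  md <- cbind(m, s5 = m[, 1])
  p <- pca_scores(md)
  expect_lt(sqrt(sum((p$scores["s1", ] - p$scores["s5", ])^2)), 1e-8)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  # 2-sample matrix: PC1 explains everything
  p2 <- pca_scores(m[, 1:2])
  expect_equal(p2$percent_variance[1], 100, tolerance = 1e-9)
  expect_error(pca_scores(m[, 1, drop = FALSE]), "2 samples")
})

test_that("DE selection applies the q and fold-change cutoffs", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(-2, -2, 2, -0.5),
                    p = c(1e-5, 0.5, 1e-5, 1e-5),
                    q = c(1e-4, 0.5, 1e-4, 1e-4),
                    stringsAsFactors = FALSE)
  expect_equal(select_de(res)$feature, c("a", "c"))
  expect_equal(select_de(res, direction = "down")$feature, "a")
  expect_equal(select_de(res, direction = "up")$feature, "c")
})
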