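test_that("mock construction draws exactly the requested genes per organism", {
  set.seed(50)
  pool <- synth_gene_catalog(5, 30, len_range = c(300, 600))
  mock <- build_mock(pool, 20, seed = 3)
  expect_equal(nrow(mock), 100L)
  expect_true(all(table(mock$org) == 20))
  expect_false(anyDuplicated(mock$gene_id) > 0)
  expect_identical(build_mock(pool, 20, seed = 3), mock)   # determinism
  # an organism with too few genes is an error naming it
  short <- pool[!(pool$org == "org2" & seq_len(nrow(pool)) %% 2 == 0), ]
  expect_error(build_mock(short, 20), "org2")
  # catalog genes are whole stop-free codon chains in their own frame
  expect_true(all(nchar(pool$seq) %% 3 == 0))
  fr <- predict_fragments(seq_set(pool$gene_id[1:5], pool$seq[1:5]), 60)
  f0 <- fr[fr$strand == "+" & fr$frame == 0 & fr$start == 0, ]
  expect_gte(nrow(f0), 5L)
})

test_that("the DE design labels exact fractions with the right folds", {
  set.seed(51)
  genes <- data.frame(gene_id = paste0("g", 1:1000),
                      seq = rep("ACGT", 1000), stringsAsFactors = FALSE)
  d <- assign_de(genes, seed = 2)
  expect_equal(sum(d$genes$label == "UP"), 200L)
  expect_equal(sum(d$genes$label == "DOWN"), 200L)
  expect_equal(sum(d$genes$label == "NULL"), 600L)
  expect_equal(unique(d$genes$fc[d$genes$label == "UP"]), 4)
  expect_equal(unique(d$genes$fc[d$genes$label == "DOWN"]), 0.25)
  # no DE at zero fractions
  d0 <- assign_de(genes, frac_up = 0, frac_down = 0)
  expect_true(all(d0$genes$label == "NULL"))
  # rounding at G = 10
  d10 <- assign_de(genes[1:10, ], seed = 1)
  expect_equal(sum(d10$genes$label == "UP"), 2L)
  expect_equal(sum(d10$genes$label == "DOWN"), 2L)
})

test_that("simulated counts follow the negative binomial design", {
  set.seed(52)
  genes <- data.frame(gene_id = paste0("g", 1:60),
                      seq = replicate(60, random_dna(900)),
                      stringsAsFactors = FALSE)
  d <- assign_de(genes, seed = 5)
  m <- simulate_counts(d, n1 = 50, n2 = 50, baseline_mean = 50,
                       dispersion = 0.2, seed = 6)
  grp <- attr(m, "groups")
  ratio <- rowMeans(m[, grp == 2]) / rowMeans(m[, grp == 1])
  lab <- d$genes$label
  # group-mean ratios approach 1 and 4 (3 sigma at n = 50, phi = 0.2)
  se_log <- sqrt(2 * (1 / 50 + 0.2) / 50)    # rough delta-method bound
  expect_true(all(abs(log(ratio[lab == "NULL"])) < 5 * se_log + 0.3))
  expect_true(abs(median(ratio[lab == "UP"]) - 4) < 1)
  expect_true(abs(median(ratio[lab == "DOWN"]) - 0.25) < 0.15)
  # dispersion 0 collapses to Poisson (variance ~ mean)
  mp <- simulate_counts(d, n1 = 200, n2 = 200, baseline_mean = 50,
                        dispersion = 0, seed = 7)
  vm <- apply(mp[, 1:200], 1, var) / rowMeans(mp[, 1:200])
  expect_lt(abs(median(vm) - 1), 0.25)
})

test_that("read simulation conserves counts and emits valid 76 nt records", {
  set.seed(53)
  genes <- data.frame(gene_id = paste0("g", 1:10),
                      seq = replicate(10, random_dna(600)),
                      stringsAsFactors = FALSE)
  d <- assign_de(genes, seed = 1)
  truth <- simulate_counts(d, n1 = 2, n2 = 2, baseline_mean = 5, seed = 2)
  reads <- simulate_reads(d, truth, flat_quality_model(76, 30), seed = 3)
  for (s in colnames(truth)) {
    expect_equal(nrow(reads[[s]]$r1), sum(truth[, s]))
    expect_equal(nrow(reads[[s]]$r2), sum(truth[, s]))
    expect_true(all(nchar(reads[[s]]$r1$seq) == 76))
    expect_true(all(unlist(phred_decode(reads[[s]]$r1$qual)) == 30))
  }
  # genes shorter than the read length are skipped with a warning
  d2 <- d; d2$genes$seq[1] <- "ACGT"
  expect_warning(simulate_reads(d2, truth, flat_quality_model(76, 30)),
                 "shorter than the read length")
})

test_that("the substitution rate matches the Phred error probability", {
  set.seed(54)
  # a homopolymer gene makes every substitution directly observable
  genes <- data.frame(gene_id = "g1", seq = strrep("A", 2000),
                      stringsAsFactors = FALSE)
  d <- assign_de(genes, frac_up = 0, frac_down = 0)
  truth <- matrix(8000L, 1, 2, dimnames = list("g1", c("g1_s1", "g2_s1")))
  attr(truth, "groups") <- c(1L, 2L)
  reads <- simulate_reads(d, truth, flat_quality_model(76, 40),
                          frag_mean = 200, frag_sd = 10, seed = 8)
  r1 <- reads[[1]]$r1
  n_base <- nrow(r1) * 76             # > 1e5 bases at Phred 40
  n_err <- sum(nchar(gsub("A", "", r1$seq)))
  p <- 1e-4
  sigma <- sqrt(p * (1 - p) / n_base)
  expect_lt(abs(n_err / n_base - p), 3 * sigma + 1e-5)
})

test_that("quality models reproduce the training distribution", {
  # constant input emits only that score
  x <- random_reads(50, 20, phred = 30)
  qm <- train_quality_model(x)
  expect_equal(unique(unlist(phred_decode(sample_quals(qm, 100)))), 30L)
  # position-dependent means match the histogram
  set.seed(55)
  quals <- vapply(1:2000, function(i)
    phred_encode(c(rep(40L, 10), sample(15:25, 10, replace = TRUE))),
    character(1))
  x2 <- seq_set(paste0("r", 1:2000),
                vapply(1:2000, function(i) random_dna(20), character(1)),
                quals)
  qm2 <- train_quality_model(x2)
  draw <- matrix(unlist(phred_decode(sample_quals(qm2, 5000))), nrow = 20)
  expect_true(all(draw[1:10, ] == 40))
  expect_lt(abs(mean(draw[11:20, ]) - 20), 0.5)
  # error contracts
  expect_error(train_quality_model(x[0, ]), "empty")
  xm <- rbind(x, seq_set("odd", "ACGT", "IIII"))
  expect_error(train_quality_model(xm), "mixed read lengths")
})

test_that("reference decontamination removes only close homologs, idempotently", {
  set.seed(56)
  src <- seq_set(paste0("s", 1:3),
                 replicate(3, random_dna(300)))
  near <- mutate_dna(src$seq[1], 6)        # 98% identity -> removed
  far <- mutate_dna(src$seq[2], 45)        # 85% identity -> retained
  cat <- seq_set(c("c1", "c2", "c3"),
                 c(near, far, random_dna(300)))
  expect_message(out <- decontaminate_reference(cat, src), "1 catalog")
  expect_equal(out$id, c("c2", "c3"))
  expect_message(out2 <- decontaminate_reference(out, src), "0 catalog")
  expect_identical(out2, out)
  # disjoint catalog unchanged
  expect_message(d0 <- decontaminate_reference(cat[3, ], src), "0 catalog")
  expect_equal(nrow(d0), 1L)
})

test_that("gene scores are one minus the nominal p-value, direction-blind", {
  de <- data.frame(feature = c("a", "b", "c", "d"),
                   log2fc = c(2, -2, 0, 1), p = c(0, 0, 1, 0.2),
                   stringsAsFactors = FALSE)
  sc <- score_genes(de)
  expect_equal(sc$score, c(1, 1, 0, 0.8))
  expect_equal(sc$score[1], sc$score[2])   # +2 and -2 at equal p tie
})

test_that("ROC/AUC agree with pairwise concordance and handle edge cases", {
  # perfectly separating scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # worked 2x2 example: 3 of 4 concordant pairs
  r <- roc_auc(c(0.9, 0.6, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_error(roc_auc(c(1, 0), c(TRUE, TRUE)), "positive and one negative")
  # brute-force concordance oracle, with ties
  set.seed(57)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    scores <- round(runif(n), 2)
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  # curves start at (0,0) and end at (1,1), monotonically
  rc <- roc_auc(runif(50), rep(c(TRUE, FALSE), 25))
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(58)
  scores <- runif(200)
  labels <- runif(200) < 0.3
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("scores independent of labels give a chance-level AUC", {
  set.seed(59)
  scores <- runif(1000)
  labels <- runif(1000) < 0.4
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("a reduced functional mock recovers the injected fold change", {
  res <- run_functional_mock(n_genes = 100, n1 = 5, n2 = 5,
                             baseline_mean = 15, seed = 11)
  expect_gt(res$auc, 0.85)
  up <- res$design$genes$gene_id[res$design$genes$label == "UP"]
  lfc <- res$de$log2fc[match(up, res$de$feature)]
  expect_gte(median(abs(lfc)), 1.5)
  expect_lte(median(abs(lfc)), 2.5)
})
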