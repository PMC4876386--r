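#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over features with a
#' nonzero count in every sample, of the ratio between the sample's count
#' and the feature's geometric mean across samples.
#'
#' @param m an abundance matrix (features x samples).
#' @param pseudocount added to every count before the ratios (default 0);
#'   use a positive value when no feature is nonzero in all samples.
#' @export
size_factors <- function(m, pseudocount = 0) {
  validate_matrix(m)
  mm <- m + pseudocount
  common <- rowSums(mm > 0) == ncol(mm)
  if (!any(common))
    stop("no feature has a nonzero count in every sample; ",
         "consider a pseudocount (size_factors(m, pseudocount = 1))")
  lg <- log(mm[common, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  sf
}

normalize_counts <- function(m, sf = NULL, pseudocount = 0) {
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(m, pseudocount),
                   error = function(e) {
                     tot <- colSums(m)
                     tot / mean(tot[tot > 0])
                   })
  }
  sweep(m, 2, sf, "/")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving
#' with the input vector.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Paired mean-of-log-ratios differential expression test
#'
#' Counts are normalized by median-of-ratios size factors; for each feature
#' and subject the log2 ratio `r_i = log2((after + pc) / (before + pc))` is
#' formed, the fold change is the mean of the `r_i`, and the p-value comes
#' from a two-sided one-sample test of the `r_i` against zero (t by
#' default). Features with all-zero normalized counts get `log2fc = 0`,
#' `p = 1`. q-values are Benjamini-Hochberg over all tested features.
#'
#' @param m an abundance matrix.
#' @param design a data frame with columns `subject`, `before`, `after`
#'   naming matrix columns; each sample appears in exactly one pair.
#' @param pseudocount added before the ratio (default 1).
#' @param test `"t"` (default) or `"wilcoxon"` (signed-rank).
#' @return A data frame with `feature`, `mean_count`, `log2fc`, `p`, `q`.
#' @export
paired_logratio_test <- function(m, design, pseudocount = 1,
                                 test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  validate_matrix(m)
  stopifnot(all(c("subject", "before", "after") %in% names(design)))
  if (nrow(design) < 2)
    stop("at least 2 subjects are required for a variance estimate")
  used <- c(design$before, design$after)
  if (anyDuplicated(used))
    stop("each sample must appear in exactly one pair")
  if (!all(used %in% colnames(m)))
    stop("design references samples absent from the matrix")
  norm <- normalize_counts(m[, used, drop = FALSE])
  before <- norm[, design$before, drop = FALSE]
  after <- norm[, design$after, drop = FALSE]
  r <- log2(after + pseudocount) - log2(before + pseudocount)
  res <- logratio_stats(r, test)
  allzero <- rowSums(before) == 0 & rowSums(after) == 0
  res$log2fc[allzero] <- 0
  res$p[allzero] <- 1
  data.frame(feature = rownames(m),
             mean_count = rowMeans(norm),
             log2fc = res$log2fc, p = res$p, q = bh_fdr(res$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

logratio_stats <- function(r, test = "t") {
  n <- ncol(r)
  lfc <- rowMeans(r)
  if (test == "t") {
    s <- apply(r, 1, sd)
    tt <- ifelse(s > 0, lfc / (s / sqrt(n)), ifelse(lfc == 0, 0, Inf))
    p <- ifelse(is.infinite(tt), 0,
                2 * pt(-abs(tt), df = n - 1))
    p[s == 0 & lfc == 0] <- 1
  } else {
    p <- apply(r, 1, function(v) {
      if (all(v == 0)) return(1)
      suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
    })
  }
  list(log2fc = lfc, p = p)
}

#' Two-group log-ratio differential expression test
#'
#' Generalization of [paired_logratio_test()] to independent groups: a
#' two-sided Welch t-test on `log2(normalized + pc)` per feature, with
#' `log2fc` = group-2 mean minus group-1 mean on that scale.
#'
#' @param m an abundance matrix.
#' @param group1,group2 character vectors of sample names.
#' @param pseudocount added before the log (default 1).
#' @return A data frame with `feature`, `mean_count`, `log2fc`, `p`, `q`.
#' @export
group_logratio_test <- function(m, group1, group2, pseudocount = 1) {
  validate_matrix(m)
  stopifnot(length(group1) >= 2, length(group2) >= 2,
            all(c(group1, group2) %in% colnames(m)))
  norm <- normalize_counts(m[, c(group1, group2), drop = FALSE])
  x <- log2(norm[, group1, drop = FALSE] + pseudocount)
  y <- log2(norm[, group2, drop = FALSE] + pseudocount)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2),
               ifelse(m2 == m1, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(is.infinite(tt), 0, 2 * pt(-abs(tt), df = df))
  p[se2 == 0 & m1 == m2] <- 1
  data.frame(feature = rownames(m), mean_count = rowMeans(norm),
             log2fc = m2 - m1, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differentially expressed features
#'
#' @param res a test result frame (with `log2fc` and `q`).
#' @param alpha q-value cutoff (default 0.01).
#' @param min_lfc absolute log2 fold-change cutoff (default 1).
#' @param direction `"both"`, `"down"` (log2fc < -min_lfc) or `"up"`.
#' @export
select_de <- function(res, alpha = 0.01, min_lfc = 1,
                      direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  sig <- res$q < alpha
  sig <- sig & switch(direction,
                      both = abs(res$log2fc) > min_lfc,
                      down = res$log2fc < -min_lfc,
                      up = res$log2fc > min_lfc)
  res[sig, , drop = FALSE]
}

#' Friedman test with tie correction
#'
#' Within-subject midranks; the tie-corrected statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (\sum_{ij} r_{ij}^2 - n k (k+1)^2 / 4)}
#' is referred to a chi-square with `k - 1` df, or to the exact permutation
#' distribution (all `(k!)^n` within-subject orderings) when `exact = TRUE`
#' and the enumeration is small enough.
#'
#' @param values numeric matrix, subjects x conditions.
#' @param exact use exact enumeration (requires `(k!)^n <= 1e6`).
#' @return A list with `statistic`, `df`, `p`, `method`.
#' @export
friedman_test <- function(values, exact = FALSE) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 2, k >= 2)
  r <- t(apply(values, 1, rank))
  stat <- friedman_stat(r, n, k)
  if (is.na(stat)) # all rows fully tied
    return(list(statistic = 0, df = k - 1, p = 1, method = "asymptotic"))
  if (exact) {
    total <- factorial(k)^n
    if (total > 1e6)
      stop("exact enumeration too large ((k!)^n = ", total, ")")
    perms <- permutations_of(seq_len(k))
    count <- 0L
    idx <- rep(1L, n)
    np <- nrow(perms)
    repeat {
      rp <- r
      for (i in seq_len(n)) rp[i, ] <- r[i, perms[idx[i], ]]
      if (friedman_stat(rp, n, k) >= stat - 1e-9) count <- count + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= np) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > n) break
    }
    return(list(statistic = stat, df = k - 1, p = count / total,
                method = "exact"))
  }
  list(statistic = stat, df = k - 1,
       p = pchisq(stat, df = k - 1, lower.tail = FALSE),
       method = "asymptotic")
}

friedman_stat <- function(r, n, k) {
  Rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0) return(NA_real_)
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  unname(out)
}

#' Spearman correlation with permutation significance
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value counts
#' permutations of `y` whose |rho| reaches the observed one. When
#' `factorial(n) <= n_perm` all permutations are enumerated (exact);
#' otherwise `n_perm` random permutations are drawn and the add-one
#' estimator `(1 + hits) / (1 + n_perm)` is used.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param n_perm permutation budget (default 10000).
#' @param seed optional integer seed for the sampled mode.
#' @return A list with `rho`, `p`, `method`.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (factorial(n) <= n_perm) {
    perms <- permutations_of(seq_len(n))
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, method = "exact"))
  }
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      rp <- cor(rx, ry[sample.int(n)])
      if (abs(rp) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(rho = rho, p = p, method = "permutation")
}

#' PCA of an abundance matrix
#'
#' Counts are normalized, transformed `log2(x + 1)` and centered per
#' feature; sample scores come from the singular value decomposition.
#' Percent variance is `sigma_i^2 / sum(sigma^2)`. Sign convention: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param m an abundance matrix (features x samples), >= 2 samples.
#' @return A list with `scores` (samples x components) and
#'   `percent_variance`.
#' @export
pca_scores <- function(m) {
  validate_matrix(m)
  if (ncol(m) < 2) stop("PCA requires at least 2 samples")
  x <- log2(normalize_counts(m) + 1)
  x <- x - rowMeans(x)
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, percent_variance = pv)
}
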