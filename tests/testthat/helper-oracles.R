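# Independent brute-force oracles and small fixture generators used across
# the suite. These deliberately re-derive every quantity from first
# principles (all-offset scans, closed forms, pairwise counting) and never
# call the package's own kernels.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_reads <- function(n, len = 76, prefix = "r", phred = 35) {
  seq_set(paste0(prefix, seq_len(n)),
          vapply(seq_len(n), function(i) random_dna(len), character(1)),
          strrep(rawToChar(as.raw(33 + phred)), len))
}

revcomp_chr <- function(s) {
  vapply(s, function(x)
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

mutate_dna <- function(s, n_mut) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n_mut)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# all-offset overlap merge oracle (mirrors the declared contract, not the code)
oracle_merge <- function(s1, q1, s2, q2, min_overlap = 8, max_diff = 0.10) {
  s2r <- revcomp_chr(s2)
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2r, "")[[1]]
  qa <- utf8ToInt(q1)
  qb <- rev(utf8ToInt(q2))
  L1 <- length(a); L2 <- length(b)
  best <- NULL
  for (d in (-(L2 - 1)):(L1 - 1)) {
    lo <- max(0, d); hi <- min(L1, d + L2); L <- hi - lo
    if (L < min_overlap) next
    ia <- (lo + 1):hi; ib <- ia - d
    mism <- sum(a[ia] != b[ib] | a[ia] == "N" | b[ib] == "N")
    if (mism > max_diff * L + 1e-9) next
    if (is.null(best) || L > best$L || (L == best$L && mism < best$m))
      best <- list(L = L, m = mism, d = d)
  }
  if (is.null(best)) return(NULL)
  d <- best$d
  lo <- min(0, d); hi <- max(L1, d + L2)
  sq <- character(hi - lo); qq <- integer(hi - lo)
  for (p in lo:(hi - 1)) {
    i <- p - lo + 1
    in1 <- p >= 0 && p < L1
    in2 <- p >= d && p < d + L2
    if (in1 && in2) {
      sq[i] <- if (qb[p - d + 1] > qa[p + 1]) b[p - d + 1] else a[p + 1]
      qq[i] <- max(qa[p + 1], qb[p - d + 1])
    } else if (in1) {
      sq[i] <- a[p + 1]; qq[i] <- qa[p + 1]
    } else {
      sq[i] <- b[p - d + 1]; qq[i] <- qb[p - d + 1]
    }
  }
  list(seq = paste(sq, collapse = ""), qual = intToUtf8(qq),
       overlap = best$L, mismatches = best$m, offset = best$d)
}

# all-diagonal ungapped identity between two sequences under the mapping
# contract (coverage relative to the query, identity threshold); returns the
# best qualifying (matches, len) by identity then length, or NULL
oracle_best_diag <- function(q, t, min_id = 90, min_cov = 0.80) {
  a <- strsplit(q, "")[[1]]; b <- strsplit(t, "")[[1]]
  La <- length(a); Lb <- length(b)
  best <- NULL
  for (d in (-(La - 1)):(Lb - 1)) {
    lo <- max(0, -d); hi <- min(La, Lb - d); L <- hi - lo
    if (L <= 0 || L < min_cov * La - 1e-9) next
    ia <- (lo + 1):hi; ib <- ia + d
    m <- sum(a[ia] == b[ib] & a[ia] != "N")
    if (100 * m < min_id * L - 1e-9) next
    better <- !is.null(best) &&
      (m * best$len > best$matches * L ||
         (m * best$len == best$matches * L && L > best$len))
    if (is.null(best) || better) best <- list(matches = m, len = L)
  }
  best
}

oracle_pair_qualifies <- function(q, t, min_id, min_cov) {
  a <- strsplit(q, "")[[1]]; b <- strsplit(t, "")[[1]]
  La <- length(a); Lb <- length(b)
  shorter <- min(La, Lb)
  for (d in (-(La - 1)):(Lb - 1)) {
    lo <- max(0, -d); hi <- min(La, Lb - d); L <- hi - lo
    if (L <= 0 || L < min_cov * shorter - 1e-9) next
    ia <- (lo + 1):hi; ib <- ia + d
    m <- sum(a[ia] == b[ib] & a[ia] != "N")
    if (100 * m >= min_id * L - 1e-9) return(TRUE)
  }
  FALSE
}

# brute-force greedy clustering (first qualifying earlier-founded cluster)
oracle_cluster <- function(seqs, min_id = 95, min_cov = 0.90) {
  ord <- order(-nchar(seqs))
  reps <- integer(0)
  asg_sorted <- integer(length(seqs))
  for (i in seq_along(ord)) {
    s <- seqs[ord[i]]
    found <- 0L
    for (ri in seq_along(reps)) {
      if (oracle_pair_qualifies(s, seqs[ord[reps[ri]]], min_id, min_cov)) {
        found <- ri
        break
      }
    }
    if (found == 0L) {
      reps <- c(reps, i)
      found <- length(reps)
    }
    asg_sorted[i] <- found
  }
  assign <- integer(length(seqs))
  assign[ord] <- asg_sorted
  assign
}

# Benjamini-Hochberg step-up closed form: q_(i) = min over j >= i of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  qo <- pmin(1, p[o] * m / seq_len(m))
  qo <- rev(cummin(rev(qo)))
  q <- numeric(m)
  q[o] <- qo
  q
}

# AUC as pairwise concordance (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exact Friedman null by full enumeration of within-row rank permutations
oracle_friedman_exact <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  r <- t(apply(values, 1, rank))
  stat_of <- function(rm) {
    Rj <- colSums(rm)
    denom <- sum(rm^2) - n * k * (k + 1)^2 / 4
    if (denom <= 0) return(0)
    (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  }
  obs <- stat_of(r)
  perms <- NULL
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  pp <- gen(seq_len(k))
  idx <- rep(1L, n)
  np <- length(pp)
  count <- 0L
  total <- 0L
  repeat {
    rm <- r
    for (i in seq_len(n)) rm[i, ] <- r[i, pp[[idx[i]]]]
    total <- total + 1L
    if (stat_of(rm) >= obs - 1e-9) count <- count + 1L
    j <- 1L
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n) break
  }
  list(statistic = obs, p = count / total)
}
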