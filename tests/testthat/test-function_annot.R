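# independent six-frame ORF scanner used as oracle
oracle_orfs <- function(s, min_len = 60) {
  rc <- revcomp_chr(s)
  out <- list()
  scan <- function(seq, strand) {
    v <- strsplit(seq, "")[[1]]
    L <- length(v)
    for (f in 0:2) {
      p <- f                      # 0-based codon start
      run_start <- f
      while (p + 2 < L) {
        cod <- paste(v[(p + 1):(p + 3)], collapse = "")
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (p - run_start >= min_len)
            out[[length(out) + 1]] <<- c(strand, f, run_start, p)
          run_start <- p + 3
        }
        p <- p + 3
      }
      if (p - run_start >= min_len)
        out[[length(out) + 1]] <<- c(strand, f, run_start, p)
    }
  }
  scan(s, "+")
  scan(rc, "-")
  if (!length(out))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(strand = m[, 1], frame = as.integer(m[, 2]),
                   start = as.integer(m[, 3]), end = as.integer(m[, 4]),
                   stringsAsFactors = FALSE)
  # map '-' coordinates back to the original read
  L <- nchar(s)
  minus <- df$strand == "-"
  st <- df$start[minus]; en <- df$end[minus]
  df$start[minus] <- L - en
  df$end[minus] <- L - st
  df
}

nonstop_codons <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

test_that("fragment prediction finds maximal stop-free codon stretches", {
  set.seed(7)
  # 66 nt of non-stop codons: frame +0 fragment covering the whole read
  s <- paste(sample(nonstop_codons, 22, replace = TRUE), collapse = "")
  fr <- predict_fragments(seq_set("r1", s), 60)
  plus0 <- fr[fr$strand == "+" & fr$frame == 0, ]
  expect_equal(nrow(plus0), 1L)
  expect_equal(c(plus0$start, plus0$end), c(0L, 66L))
  expect_equal(plus0$seq, s)
  # 30 nt read: below the minimum, no fragment
  expect_equal(nrow(predict_fragments(seq_set("r1", random_dna(30)), 60)), 0L)
  # all extents are whole codons of at least min length
  r <- random_reads(20, 150)
  fr <- predict_fragments(r, 60)
  expect_true(all((fr$end - fr$start) %% 3 == 0))
  expect_true(all(fr$end - fr$start >= 60))
  expect_true(all(nchar(fr$seq) == fr$end - fr$start))
})

test_that("fragment prediction matches an independent six-frame oracle", {
  set.seed(8)
  for (i in 1:30) {
    s <- random_dna(sample(60:250, 1))
    got <- predict_fragments(seq_set("r", s), 60)
    want <- oracle_orfs(s, 60)
    key <- function(d) sort(paste(d$strand, d$frame, d$start, d$end))
    expect_equal(key(got), key(want), info = paste("read", i))
  }
})

test_that("reads whose frames all stop early are discarded", {
  # (TTAA)^30: stops recur every few codons in all six frames (the repeat is
  # its own reverse complement), so no stop-free stretch reaches 60 nt
  s <- strrep("TTAA", 30)
  expect_equal(nrow(oracle_orfs(s, 60)), 0L)
  expect_equal(nrow(predict_fragments(seq_set("r", s), 60)), 0L)
})

frag_df <- function(seqs, copies = 1L) {
  data.frame(read_id = paste0("f", seq_along(seqs)), seq = seqs,
             copies = rep_len(copies, length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("greedy clustering honors the identity and coverage thresholds", {
  set.seed(10)
  base <- random_dna(100)
  # identical pair -> one cluster of weight 2
  cl <- cluster_greedy(frag_df(c(base, base)))
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$weight, 2L)
  expect_equal(cl$reps$csize, 2L)
  expect_equal(cl$reps$copies, 1L)
  # 4 mismatches in 100 (96%) co-clusters; 6 (94%) does not
  expect_equal(nrow(cluster_greedy(frag_df(c(base, mutate_dna(base, 4))))$clusters), 1L)
  expect_equal(nrow(cluster_greedy(frag_df(c(base, mutate_dna(base, 6))))$clusters), 2L)
  # coverage: fragment matching only 60 of its own 100 nt founds a new cluster
  part <- paste0(substr(base, 41, 100), random_dna(40))
  expect_equal(nrow(cluster_greedy(frag_df(c(base, part)))$clusters), 2L)
  # weight conservation with copies
  seqs <- c(base, mutate_dna(base, 2), random_dna(80))
  cl <- cluster_greedy(frag_df(seqs, copies = c(3L, 2L, 5L)))
  expect_equal(sum(cl$clusters$weight), 10L)
  expect_true(all(cl$clusters$weight >= cl$clusters$size))
  # member-cardinality mode
  clm <- cluster_greedy(frag_df(seqs, copies = c(3L, 2L, 5L)),
                        csize_mode = "members")
  expect_equal(sum(clm$clusters$weight), 3L)
})

test_that("greedy clustering matches the brute-force all-pairs oracle", {
  set.seed(11)
  # families of mutated copies at assorted lengths + unrelated sequences
  seqs <- character(0)
  for (fam in 1:12) {
    root <- random_dna(sample(c(60, 80, 120, 200), 1))
    seqs <- c(seqs, root)
    for (m in seq_len(sample(2:5, 1)))
      seqs <- c(seqs, mutate_dna(root, sample(0:8, 1)))
  }
  seqs <- c(seqs, vapply(1:15, function(i) random_dna(sample(60:150, 1)),
                         character(1)))
  got <- cluster_greedy(frag_df(seqs))$assignment
  want <- oracle_cluster(seqs)
  expect_identical(got, want)
})

test_that("best-hit mapping returns the top identity hit with fixed tie-breaks", {
  set.seed(12)
  genes <- seq_set(c("g2", "g1", "g3"),
                   c(random_dna(300), random_dna(300), random_dna(300)))
  cat <- gene_catalog(genes)
  q <- substr(genes$seq[1], 50, 125)    # exact substring of g2
  hit <- map_best_hit(seq_set("q1", q), cat)
  expect_equal(hit$gene_id, "g2")
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 1)
  # duplicated catalog entry: lexicographically smallest gene id wins
  dup <- gene_catalog(seq_set(c("gB", "gA"),
                              rep(genes$seq[1], 2)))
  hit <- map_best_hit(seq_set("q1", q), dup)
  expect_equal(hit$gene_id, "gA")
  # ~70% identity is below the default 90% threshold -> unmapped
  far <- mutate_dna(substr(genes$seq[1], 1, 76), 23)
  expect_true(is.na(map_best_hit(seq_set("q1", far), cat)$gene_id))
  # reverse-strand queries map when both_strands is on
  hit <- map_best_hit(seq_set("q1", revcomp_chr(q)), cat)
  expect_equal(hit$gene_id, "g2")
  expect_equal(hit$strand, "-")
  expect_error(gene_catalog(genes[0, ]), "empty")
})

test_that("returned hit identities are reproduced by a full-alignment oracle", {
  set.seed(13)
  genes <- seq_set(paste0("g", 1:20),
                   vapply(1:20, function(i) random_dna(400), character(1)))
  cat <- gene_catalog(genes)
  for (i in 1:60) {
    g <- sample(20, 1)
    st <- sample(300, 1)
    q <- mutate_dna(substr(genes$seq[g], st, st + 75), sample(0:5, 1))
    if (runif(1) < 0.5) q <- revcomp_chr(q)
    hit <- map_best_hit(seq_set("q", q), cat)
    expect_false(is.na(hit$gene_id))
    tseq <- genes$seq[match(hit$gene_id, genes$id)]
    qs <- if (hit$strand == "-") revcomp_chr(q) else q
    want <- oracle_best_diag(qs, tseq)
    expect_false(is.null(want))
    expect_equal(hit$identity, 100 * want$matches / want$len)
    expect_equal(hit$coverage, want$len / nchar(q))
  }
})

test_that("count aggregation weights hits by copies x csize and de-duplicates", {
  h1 <- data.frame(query_id = c("a", "b", "b"),
                   gene_id = c("G1", "G1", "G2"),
                   identity = 100, coverage = 1, strand = "+",
                   copies = c(3L, 1L, 1L), csize = c(2L, 4L, 4L),
                   stringsAsFactors = FALSE)
  expect_warning(m <- aggregate_counts(list(s1 = h1)), "duplicate")
  expect_equal(m["G1", "s1"], 3 * 2 + 1 * 4)   # duplicate b->G2 dropped
  # no hits -> all-zero matrix over the fixed feature space
  h0 <- h1[0, ]
  m0 <- aggregate_counts(list(s1 = h0), features = c("G1", "G2"))
  expect_true(all(m0 == 0))
  expect_equal(dim(m0), c(2L, 1L))
  # two queries with weights 1 and 4
  h2 <- data.frame(query_id = c("a", "b"), gene_id = "G1", identity = 100,
                   coverage = 1, strand = "+", copies = c(1L, 4L),
                   csize = c(1L, 1L), stringsAsFactors = FALSE)
  expect_equal(aggregate_counts(list(S = h2))["G1", "S"], 5)
})

test_that("rollup sums genes into groups and categories with an unknown sink", {
  ann <- data.frame(gene_id = c("g1", "g2", "g4", "g5", "g6", "gX"),
                    og_id = c("OG1", "OG1", "OG2", "OG3", "OG4", "OG9"),
                    ko_id = c("K1", "K1", "K2", "", "K3", ""),
                    category = c("E", "E", "E", "E", "G", "Z"),
                    stringsAsFactors = FALSE)
  m <- matrix(c(2, 3, 7, 1, 2, 3), ncol = 1,
              dimnames = list(c("g1", "g2", "g3", "g4", "g5", "g6"), "s1"))
  expect_warning(ru <- rollup(m, ann), "absent")
  expect_equal(ru$og["OG1", "s1"], 5)          # 2 + 3
  expect_equal(ru$og["unknown", "s1"], 7)      # unannotated g3
  expect_equal(ru$category["E", "s1"], 5 + 1 + 2)
  expect_equal(sum(ru$og), sum(m))             # conservation
  expect_equal(sum(ru$category), sum(m))
})
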