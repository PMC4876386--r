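#' Score genes for ROC construction
#'
#' Each feature gets `score = 1 - p` (the nominal p-value, not the
#' q-value); the score is two-sided, ignoring the direction of change.
#'
#' @param de a differential-expression result frame with `feature` and `p`.
#' @export
score_genes <- function(de) {
  data.frame(feature = de$feature, score = 1 - de$p,
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' Sweeps all unique score thresholds, computing the true- and
#' false-positive rates with the simulated DE features as positives; AUC is
#' the trapezoid area, equal to the midrank Mann-Whitney statistic under
#' ties.
#'
#' @param scores numeric score vector.
#' @param labels logical vector (`TRUE` = positive), same length.
#' @return A `roc_curve` list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0)
    stop("ROC requires at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l); cum_fp <- cumsum(!l)
  last <- cumsum(rle(s)$lengths)       # last index of each threshold block
  tpr <- c(0, cum_tp[last] / P)
  fpr <- c(0, cum_fp[last] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

# run one sample of mRNA-bound reads through qc -> sort -> merge -> gene
# fragments -> clustering -> best-hit mapping; returns the per-sample hits
quantify_sample <- function(r1, r2, catalog, idx = NULL,
                            tpol = trim_policy(), mpol = merge_policy(),
                            min_orf_len = 60L, cluster_id = 95,
                            cluster_cov = 0.90, map_id = 90, map_cov = 0.80) {
  fp <- filter_pairs(r1, r2, tpol)
  cp <- collapse_pairs(fp$r1, fp$r2)
  if (!is.null(idx)) {
    buckets <- sort_pairs(cp$r1, cp$r2, idx)
    mr1 <- buckets$MRNA$r1; mr2 <- buckets$MRNA$r2
  } else {
    mr1 <- cp$r1; mr2 <- cp$r2
  }
  mg <- merge_pairs(mr1, mr2, mpol)
  queries <- rbind(mg$merged, mg$unmerged1, mg$unmerged2)
  frags <- predict_fragments(queries, min_orf_len)
  if (nrow(frags) == 0)
    return(map_best_hit(seq_set(character(0), character(0)), catalog))
  cl <- cluster_greedy(frags, min_id = cluster_id, min_cov = cluster_cov)
  map_best_hit(cl$reps, catalog, min_id = map_id, min_cov = map_cov)
}

#' Functional mock-community experiment
#'
#' End-to-end validation harness: a synthetic gene set is drawn, a
#' fraction of genes gets a fold-change between two groups, negative
#' binomial truth counts and error-bearing paired reads are simulated, the
#' reads are pushed through the full quantification pipeline (quality
#' filtering, pair collapsing, rRNA sorting, overlap merging, gene-fragment
#' prediction, greedy clustering, best-hit catalog mapping,
#' cluster-weighted counting), genes are tested for differential
#' expression, scored by `1 - p`, and ranked against the simulated truth
#' with a ROC curve.
#'
#' @param n_genes total mock genes (default 1000, drawn equally from 5
#'   synthetic organisms).
#' @param n1,n2 samples per group (default 10).
#' @param frac_up,frac_down,fold the DE design (default 20% / 20% / 4).
#' @param baseline_mean mean read pairs per average gene (default 20).
#' @param dispersion NB dispersion (default 0.2).
#' @param read_len,frag_mean,frag_sd read simulation geometry.
#' @param qm quality model (default: flat Phred 30).
#' @param include_sort classify reads against a synthetic rRNA index before
#'   quantification (default TRUE).
#' @param seed integer seed for the whole experiment.
#' @return A list with `auc`, `roc`, `de`, `design`, `counts` (the
#'   pipeline-derived matrix) and `truth_counts`.
#' @export
run_functional_mock <- function(n_genes = 1000L, n1 = 10L, n2 = 10L,
                                frac_up = 0.20, frac_down = 0.20, fold = 4,
                                baseline_mean = 20, dispersion = 0.2,
                                read_len = 76L, frag_mean = 250,
                                frag_sd = 25, qm = NULL,
                                include_sort = TRUE, seed = 1L) {
  if (is.null(qm)) qm <- flat_quality_model(read_len, 30L)
  withr::with_seed(seed, {
    per_org <- ceiling(n_genes / 5)
    pool <- synth_gene_catalog(5L, 2L * per_org)
    genes <- build_mock(pool, per_org)
    genes <- genes[seq_len(n_genes), , drop = FALSE]
    design <- assign_de(genes, frac_up, frac_down, fold)
    catalog <- gene_catalog(seq_set(genes$gene_id, genes$seq))
    truth <- simulate_counts(design, n1, n2, baseline_mean, dispersion)
    reads <- simulate_reads(design, truth, qm, read_len, frag_mean, frag_sd)
    idx <- NULL
    if (include_sort) {
      rand_ref <- function(n, L) seq_set(
        paste0("ref", seq_len(n)),
        vapply(seq_len(n), function(i)
          paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = ""), character(1)))
      idx <- build_kmer_index(list(SSU = rand_ref(2, 1500),
                                   LSU = rand_ref(2, 2900),
                                   FIVE_S = rand_ref(2, 120),
                                   TRNA = rand_ref(4, 80)))
    }
    hits <- lapply(reads, function(pp)
      suppressWarnings(quantify_sample(pp$r1, pp$r2, catalog, idx)))
    m <- suppressWarnings(aggregate_counts(hits, features = genes$gene_id))
    g1 <- colnames(truth)[attr(truth, "groups") == 1L]
    g2 <- colnames(truth)[attr(truth, "groups") == 2L]
    de <- group_logratio_test(m, g1, g2)
    sc <- score_genes(de)
    truth_pos <- design$genes$label[match(sc$feature, design$genes$gene_id)] != "NULL"
    roc <- roc_auc(sc$score, truth_pos)
    list(auc = roc$auc, roc = roc, de = de, design = design, counts = m,
         truth_counts = truth)
  })
}

#' Taxonomic 16S mock-community experiment
#'
#' The same DE design applied to a synthetic lineage-labelled 16S
#' community: reads are simulated from the reference sequences, pushed
#' through the taxonomy pipeline (quality filtering, collapsing, overlap
#' merging, reservoir subsampling, 97% clustering, best-hit lineage
#' assignment, species-rank tables), species are tested for differential
#' abundance and ranked against the truth with a ROC curve. Organisms never
#' observed in the tables score 0.
#'
#' @param n_organisms number of reference organisms (default 200).
#' @param n1,n2 samples per group (default 10).
#' @param frac_up,frac_down,fold the DE design.
#' @param baseline_mean mean read pairs per organism and sample (default 30).
#' @param dispersion NB dispersion (default 0.2).
#' @param read_len read length (default 76).
#' @param frag_mean,frag_sd 16S library fragment geometry (default 130 +-
#'   15, so most pairs overlap by at least 8 bp).
#' @param subsample reservoir capacity (default 100000).
#' @param otu_id identity used for pre-mapping clustering (default 97).
#' @param qm quality model (default flat Phred 30).
#' @param seed integer seed.
#' @return A list with `auc`, `roc`, `de`, `design`, `tables`.
#' @export
run_taxonomic_mock <- function(n_organisms = 200L, n1 = 10L, n2 = 10L,
                               frac_up = 0.20, frac_down = 0.20, fold = 4,
                               baseline_mean = 30, dispersion = 0.2,
                               read_len = 76L, frag_mean = 130,
                               frag_sd = 15, subsample = 100000L,
                               otu_id = 97, qm = NULL, seed = 1L) {
  if (is.null(qm)) qm <- flat_quality_model(read_len, 30L)
  withr::with_seed(seed, {
    refs <- synth_16s_community(n_organisms)
    genes <- data.frame(gene_id = refs$id, seq = refs$seq,
                        stringsAsFactors = FALSE)
    design <- assign_de(genes, frac_up, frac_down, fold)
    truth <- simulate_counts(design, n1, n2, baseline_mean, dispersion)
    reads <- simulate_reads(design, truth, qm, read_len, frag_mean, frag_sd)
    assignments <- lapply(reads, function(pp) {
      fp <- filter_pairs(pp$r1, pp$r2)
      cp <- collapse_pairs(fp$r1, fp$r2)
      mg <- merge_pairs(cp$r1, cp$r2)
      sub <- reservoir_sample(mg$merged, subsample)
      if (nrow(sub) == 0)
        return(assign_lineage(sub, refs))
      cl <- cluster_greedy(sub, min_id = otu_id, min_cov = 0.90)
      assign_lineage(cl$reps, refs)
    })
    tables <- build_rank_tables(assignments)
    sp <- tables$species
    g1 <- colnames(truth)[attr(truth, "groups") == 1L]
    g2 <- colnames(truth)[attr(truth, "groups") == 2L]
    keep <- intersect(colnames(sp), c(g1, g2))
    de <- group_logratio_test(sp, intersect(g1, keep), intersect(g2, keep))
    sc <- score_genes(de)
    score <- rep(0, nrow(refs))
    hit <- match(refs$lineage, sc$feature)
    score[!is.na(hit)] <- sc$score[hit[!is.na(hit)]]
    truth_pos <- design$genes$label != "NULL"
    roc <- roc_auc(score, truth_pos)
    list(auc = roc$auc, roc = roc, de = de, design = design,
         tables = tables)
  })
}
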