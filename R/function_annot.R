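#' Predict gene fragments
#'
#' A six-frame maximal-ORF caller: every maximal stop-free stretch of whole
#' codons of at least `min_orf_len` nt (standard-code stops TAA/TAG/TGA) is
#' emitted as a putative gene fragment; reads that yield none are discarded.
#' Fragment coordinates are 0-based half-open on the source read, and minus
#' strand fragments carry the reverse-complemented (coding) sequence.
#'
#' @param x a sequence set.
#' @param min_orf_len minimum fragment length in nt (default 60).
#' @return A data frame with columns `read_id`, `strand`, `frame`, `start`,
#'   `end`, `seq`, and the inherited `copies`/`csize` tags.
#' @export
predict_fragments <- function(x, min_orf_len = 60L) {
  validate_seq_set(x)
  if (nrow(x) == 0)
    return(data.frame(read_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      copies = integer(0), csize = integer(0),
                      stringsAsFactors = FALSE))
  fr <- cpp_predict_fragments(x$seq, as.integer(min_orf_len))
  data.frame(read_id = x$id[fr$read], strand = fr$strand, frame = fr$frame,
             start = fr$start, end = fr$end, seq = fr$seq,
             copies = x$copies[fr$read], csize = x$csize[fr$read],
             stringsAsFactors = FALSE)
}

#' Greedy identity clustering
#'
#' CD-HIT-style incremental clustering: fragments are sorted by length
#' descending (stable) and each joins the earliest-founded cluster whose
#' representative aligns at `min_id` percent identity over at least
#' `min_cov` of the shorter sequence, else founds a new cluster. Cluster
#' weight is the sum of member `copies`; representatives are re-emitted with
#' `csize` equal to that weight (and `copies` reset to 1, so downstream
#' weights are `copies * csize`).
#'
#' @param frags a fragment data frame (from [predict_fragments()]) or any
#'   data frame with `seq` and `copies` columns; a `read_id` or `id` column
#'   names the members.
#' @param min_id identity threshold in percent (default 95).
#' @param min_cov minimum overlap as a fraction of the shorter sequence
#'   (default 0.90).
#' @param word word length of the candidate filter (default 11; lossless at
#'   the default thresholds).
#' @param csize_mode `"copies"` (weight = sum of member copy counts, the
#'   default) or `"members"` (plain member cardinality).
#' @return A list with `assignment` (cluster id per input row, founding
#'   order), `clusters` (id, rep row, rep id, size, weight) and `reps` (a
#'   sequence set of representatives tagged with `csize`).
#' @export
cluster_greedy <- function(frags, min_id = 95, min_cov = 0.90, word = 11L,
                           csize_mode = c("copies", "members")) {
  csize_mode <- match.arg(csize_mode)
  idcol <- if ("read_id" %in% names(frags)) "read_id" else "id"
  seqs <- frags$seq
  copies <- if ("copies" %in% names(frags)) frags$copies else rep(1L, length(seqs))
  n <- length(seqs)
  if (n == 0)
    return(list(assignment = integer(0),
                clusters = data.frame(cluster = integer(0),
                                      rep_row = integer(0),
                                      rep_id = character(0),
                                      size = integer(0), weight = integer(0),
                                      stringsAsFactors = FALSE),
                reps = seq_set(character(0), character(0))))
  ord <- order(-nchar(seqs))            # stable: ties keep input order
  asg_sorted <- cpp_cluster_greedy(seqs[ord], min_id, min_cov,
                                   as.integer(word))
  assignment <- integer(n)
  assignment[ord] <- asg_sorted
  rep_row <- ord[match(seq_len(max(assignment)), asg_sorted)]
  size <- tabulate(assignment)
  weight <- if (csize_mode == "copies")
    as.integer(rowsum(as.numeric(copies), assignment)[as.character(seq_len(max(assignment))), 1])
  else size
  clusters <- data.frame(cluster = seq_along(rep_row), rep_row = rep_row,
                         rep_id = as.character(frags[[idcol]][rep_row]),
                         size = size, weight = weight,
                         stringsAsFactors = FALSE)
  reps <- seq_set(clusters$rep_id, seqs[rep_row], NA_character_,
                  copies = 1L, csize = weight)
  list(assignment = assignment, clusters = clusters, reps = reps)
}

#' Gene catalogs
#'
#' A catalog couples reference gene sequences with an optional annotation
#' map (orthologous group, KO, one-letter functional category). Entries are
#' kept sorted by `gene_id` so that best-hit ties resolve to the
#' lexicographically smallest gene id.
#'
#' @param genes a sequence set or FASTA path of catalog genes.
#' @param annotation an annotation data frame (see [read_annotation()]) or
#'   TSV path, or `NULL`.
#' @export
gene_catalog <- function(genes, annotation = NULL) {
  if (is.character(genes)) genes <- read_fasta(genes)
  if (nrow(genes) == 0) stop("gene catalog is empty")
  if (anyDuplicated(genes$id)) stop("catalog gene ids must be unique")
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  genes <- genes[order(genes$id), , drop = FALSE]
  structure(list(genes = genes, annotation = annotation),
            class = "gene_catalog")
}

#' Best-hit mapping against a catalog
#'
#' Seed-and-extend nucleotide mapping: candidate targets share at least one
#' `seed_k`-mer with the query (either strand); candidates are scored by
#' ungapped identity over the seeded diagonal. Among qualifying candidates
#' the hit with the highest identity wins (ties: longer alignment, then
#' lexicographically smallest gene id). One best hit is retained per query.
#'
#' @param queries a sequence set (or character vector).
#' @param catalog a [gene_catalog()] (or a sequence set of targets).
#' @param min_id minimum percent identity (default 90).
#' @param min_cov minimum aligned fraction of the query (default 0.80).
#' @param seed_k seed k-mer length (default 15).
#' @param both_strands also try the reverse-complemented query (default TRUE).
#' @return A data frame with one row per query: `query_id`, `gene_id` (`NA`
#'   when unmapped), `identity` (percent), `coverage`, `strand`, plus the
#'   query `copies`/`csize` tags.
#' @export
map_best_hit <- function(queries, catalog, min_id = 90, min_cov = 0.80,
                         seed_k = 15L, both_strands = TRUE) {
  if (inherits(catalog, "gene_catalog")) {
    tgt <- catalog$genes
  } else if (is.data.frame(catalog)) {
    if (nrow(catalog) == 0) stop("gene catalog is empty")
    tgt <- catalog[order(catalog$id), , drop = FALSE]
  } else stop("'catalog' must be a gene_catalog or a sequence set")
  qdf <- if (is.data.frame(queries)) queries else seq_set(
    paste0("q", seq_along(queries)), queries)
  res <- cpp_map_best_hit(qdf$seq, tgt$seq, min_id, min_cov,
                          as.integer(seed_k), both_strands, FALSE)
  data.frame(query_id = qdf$id,
             gene_id = ifelse(res$target == 0L, NA_character_,
                              tgt$id[pmax(res$target, 1L)]),
             identity = res$identity, coverage = res$coverage,
             strand = res$strand,
             copies = qdf$copies, csize = qdf$csize,
             stringsAsFactors = FALSE)
}

#' Cluster-weighted count aggregation
#'
#' Builds the gene-by-sample abundance matrix from per-sample best hits.
#' Each mapped query contributes `copies * csize` to its gene; duplicate
#' hits sharing a query id within a sample are dropped (with a warning), so
#' each query counts at most once.
#'
#' @param hits_by_sample named list (one element per sample) of
#'   [map_best_hit()] data frames.
#' @param features optional character vector fixing the row space (e.g. all
#'   catalog gene ids); defaults to the union of hit genes.
#' @export
aggregate_counts <- function(hits_by_sample, features = NULL) {
  stopifnot(is.list(hits_by_sample), !is.null(names(hits_by_sample)))
  samples <- names(hits_by_sample)
  per_sample <- lapply(hits_by_sample, function(h) {
    h <- h[!is.na(h$gene_id), , drop = FALSE]
    dup <- duplicated(h$query_id)
    if (any(dup)) {
      warning(sum(dup), " duplicate hit(s) from already-counted query ids dropped")
      h <- h[!dup, , drop = FALSE]
    }
    w <- as.numeric(h$copies) * as.numeric(h$csize)
    tapply(w, h$gene_id, sum)
  })
  if (is.null(features))
    features <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0, nrow = length(features), ncol = length(samples),
              dimnames = list(features, samples))
  for (s in samples) {
    v <- per_sample[[s]]
    v <- v[names(v) %in% features]
    m[names(v), s] <- v
  }
  validate_matrix(m)
  m
}

#' Roll gene counts up to orthologous groups and functional categories
#'
#' Orthologous-group counts are sums of member gene counts; category counts
#' are sums of member orthologous-group counts. Genes (or groups) without an
#' annotation accumulate under the `unknown` feature, so totals are
#' conserved.
#'
#' @param m a gene-level abundance matrix.
#' @param annotation an annotation data frame (see [read_annotation()]).
#' @return A list with `og` and `category` abundance matrices.
#' @export
rollup <- function(m, annotation) {
  validate_matrix(m)
  ann <- annotation[match(rownames(m), annotation$gene_id), , drop = FALSE]
  orphan <- setdiff(annotation$gene_id, rownames(m))
  if (length(orphan))
    warning(length(orphan), " annotation entr(ies) reference genes absent ",
            "from the matrix and were ignored")
  og <- ann$og_id
  og[is.na(og) | og == ""] <- "unknown"
  og_m <- rowsum(m, group = og)
  og_m <- og_m[order(rownames(og_m)), , drop = FALSE]
  og2cat <- annotation$category[match(rownames(og_m), annotation$og_id)]
  og2cat[is.na(og2cat) | og2cat == ""] <- "unknown"
  cat_m <- rowsum(og_m, group = og2cat)
  cat_m <- cat_m[order(rownames(cat_m)), , drop = FALSE]
  list(og = og_m, category = cat_m)
}

#' Export KO ids of selected features
#'
#' Writes the newline-separated KO ids of the given genes (e.g. a
#' differential-expression selection) for pathway-map tools.
#'
#' @param gene_ids character vector of selected gene ids.
#' @param annotation an annotation data frame.
#' @param path output file.
#' @export
export_kos <- function(gene_ids, annotation, path) {
  ko <- annotation$ko_id[match(gene_ids, annotation$gene_id)]
  ko <- unique(ko[!is.na(ko) & ko != ""])
  writeLines(ko, path)
  invisible(ko)
}
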