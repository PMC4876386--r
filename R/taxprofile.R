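LINEAGE_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
LINEAGE_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                   "genus", "species")

#' Parse Greengenes-style lineage strings
#'
#' A lineage is seven `; `-separated rank fields with the prefixes
#' `k__ p__ c__ o__ f__ g__ s__`; an empty field after its prefix means the
#' rank is unknown.
#'
#' @param lineage character vector of lineage strings.
#' @return A character matrix with one column per rank (prefixes retained);
#'   unknown ranks are empty strings.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";[[:space:]]*")
  out <- matrix("", nrow = length(lineage), ncol = 7,
                dimnames = list(NULL, LINEAGE_RANKS))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 7L)
      stop("malformed lineage (record ", i, "): expected 7 ranks, got ",
           length(p))
    if (!all(substr(p, 1, 3) == LINEAGE_PREFIXES))
      stop("malformed lineage (record ", i, "): bad rank prefixes")
    out[i, ] <- ifelse(nchar(p) > 3L, p, "")
  }
  out
}

#' Read a 16S reference with lineage headers
#'
#' FASTA headers of the form `>id<TAB>k__...; p__...; ...; s__...`
#' (Greengenes dialect).
#'
#' @param path FASTA file path.
#' @return A data frame with `id`, `seq`, `lineage` plus the seven parsed
#'   rank columns.
#' @export
read_16s_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub("\t.*$", "", hdr)
  lineage <- ifelse(grepl("\t", hdr), sub("^[^\t]*\t", "", hdr), NA_character_)
  if (any(is.na(lineage)))
    stop("malformed 16S reference header (record ",
         which(is.na(lineage))[1], "): missing tab-separated lineage")
  ranks <- parse_lineage(lineage)
  df <- data.frame(id = id, seq = as.character(ss), lineage = lineage,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(ranks, stringsAsFactors = FALSE))
}

#' Reservoir subsampling of reads
#'
#' Single-pass Algorithm R: every input record is retained with equal
#' probability `capacity / n`, without replacement; deterministic for a
#' given seed.
#'
#' @param x a sequence set (or any data frame).
#' @param capacity reservoir size (default 100000).
#' @param seed optional integer seed.
#' @export
reservoir_sample <- function(x, capacity = 100000L, seed = NULL) {
  stopifnot(capacity >= 1L)
  n <- nrow(x)
  if (n <= capacity) return(x)
  run <- function() {
    res <- seq_len(capacity)
    j <- floor(runif(n - capacity) * ((capacity + 1):n)) + 1L
    for (i in seq_along(j))
      if (j[i] <= capacity) res[j[i]] <- capacity + i
    res
  }
  idx <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign lineages by best-hit 16S mapping
#'
#' @param queries a sequence set.
#' @param ref a [read_16s_reference()] data frame.
#' @param min_id,min_cov,seed_k best-hit thresholds (see [map_best_hit()]).
#' @return One row per query: `query_id`, `ref_id` (`NA` = unclassified),
#'   `identity`, `coverage`, weight tags and the seven rank columns.
#' @export
assign_lineage <- function(queries, ref, min_id = 90, min_cov = 0.80,
                           seed_k = 15L) {
  tgt <- seq_set(ref$id, ref$seq)
  hits <- map_best_hit(queries, tgt, min_id = min_id, min_cov = min_cov,
                       seed_k = seed_k, both_strands = TRUE)
  ref_sorted <- ref[order(ref$id), , drop = FALSE]
  ri <- match(hits$gene_id, ref_sorted$id)
  ranks <- as.data.frame(
    matrix("", nrow = nrow(hits), ncol = 7,
           dimnames = list(NULL, LINEAGE_RANKS)),
    stringsAsFactors = FALSE)
  known <- !is.na(ri)
  for (r in LINEAGE_RANKS) ranks[[r]][known] <- ref_sorted[[r]][ri[known]]
  data.frame(query_id = hits$query_id, ref_id = hits$gene_id,
             identity = hits$identity, coverage = hits$coverage,
             copies = hits$copies, csize = hits$csize, ranks,
             stringsAsFactors = FALSE)
}

#' Build per-rank abundance tables
#'
#' For each of the seven ranks, assignments are grouped by their lineage
#' truncated to that rank (unknown ranks group under the deepest known
#' prefix) and weighted by `copies * csize`. After construction, per-cell
#' singletons (count of exactly 1 within a sample) are zeroed, and rows are
#' sorted by decreasing mean abundance.
#'
#' @param assignments named list (one per sample) of [assign_lineage()]
#'   frames; unclassified queries are skipped.
#' @param remove_singletons zero out cells equal to 1 (default TRUE).
#' @return A named list of seven abundance matrices, `kingdom` to `species`.
#' @export
build_rank_tables <- function(assignments, remove_singletons = TRUE) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  samples <- names(assignments)
  out <- vector("list", 7)
  names(out) <- LINEAGE_RANKS
  for (r in seq_len(7)) {
    per_sample <- lapply(assignments, function(a) {
      a <- a[!is.na(a$ref_id), , drop = FALSE]
      if (nrow(a) == 0) return(numeric(0))
      ranks <- as.matrix(a[, LINEAGE_RANKS[seq_len(r)], drop = FALSE])
      feat <- apply(ranks, 1, function(v) {
        known <- nchar(v) > 3L        # "g__" or "" means unknown
        cut <- which(!known)
        if (length(cut)) v <- v[seq_len(cut[1] - 1L)]
        if (length(v) == 0) "unknown" else paste(v, collapse = "; ")
      })
      w <- as.numeric(a$copies) * as.numeric(a$csize)
      tapply(w, feat, sum)
    })
    feats <- sort(unique(unlist(lapply(per_sample, names))))
    m <- matrix(0, nrow = length(feats), ncol = length(samples),
                dimnames = list(feats, samples))
    for (s in samples) {
      v <- per_sample[[s]]
      if (length(v)) m[names(v), s] <- v
    }
    if (remove_singletons) m[m == 1] <- 0
    m <- m[order(-rowMeans(m)), , drop = FALSE]
    out[[r]] <- m
  }
  out
}

#' Filter taxa by minimum relative abundance
#'
#' Keeps a feature when its relative abundance reaches `min_frac` in at
#' least one sample. Zero-total samples are excluded from the maximum with
#' a warning.
#'
#' @param m an abundance matrix.
#' @param min_frac minimum within-sample fraction (e.g. 0.01 or 0.002).
#' @export
filter_taxa <- function(m, min_frac) {
  validate_matrix(m)
  stopifnot(min_frac >= 0, min_frac <= 1)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total sample(s) excluded from the ",
            "abundance maximum")
  }
  use <- tot > 0
  if (!any(use)) return(m[integer(0), , drop = FALSE])
  rel <- sweep(m[, use, drop = FALSE], 2, tot[use], "/")
  keep <- apply(rel, 1, max) >= min_frac
  m[keep, , drop = FALSE]
}

#' Rarefy an abundance table
#'
#' Each sample with at least `depth` total counts is subsampled without
#' replacement (multivariate hypergeometric) to exactly `depth`; samples
#' below depth are dropped with a warning. Deterministic for a given seed.
#'
#' @param m an abundance matrix (features x samples).
#' @param depth target per-sample total (default 1952).
#' @param seed optional integer seed.
#' @export
rarefy <- function(m, depth = 1952L, seed = NULL) {
  validate_matrix(m)
  stopifnot(depth >= 1L)
  tot <- colSums(m)
  drop <- tot < depth
  if (any(drop))
    warning(sum(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(m)[drop], collapse = ", "))
  keep <- m[, !drop, drop = FALSE]
  if (ncol(keep) == 0) return(keep)
  # vegan warns whenever the smallest count exceeds 1; inputs here are
  # validated count matrices, so that advisory is noise
  run <- function() withCallingHandlers(
    t(vegan::rrarefy(t(keep), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dimnames(out) <- dimnames(keep)
  out
}
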