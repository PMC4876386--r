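#' Quality trimming policy
#'
#' Reads are trimmed by removing leading/trailing runs of N
#' (cluster-N regions), then dropping the longest 3' suffix whose bases all
#' fall below `min_phred`; reads shorter than `min_len` afterwards are
#' rejected.
#'
#' @param min_phred minimum Phred score retained at the 3' end (default 10).
#' @param min_len minimum surviving read length in nt (default 30).
#' @param trim_cluster_n strip leading/trailing N runs first (default TRUE).
#' @param adapter optional 3' adapter sequence; when set, the earliest exact
#'   match of at least 8 bp between a read suffix and the adapter's prefix
#'   is clipped before any other trimming. Off by default.
#' @export
trim_policy <- function(min_phred = 10L, min_len = 30L,
                        trim_cluster_n = TRUE, adapter = NULL) {
  stopifnot(min_phred >= 0L, min_len >= 1L)
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    stopifnot(nchar(adapter) >= 8L, !grepl("[^ACGTN]", adapter))
  }
  structure(list(min_phred = as.integer(min_phred),
                 min_len = as.integer(min_len),
                 trim_cluster_n = isTRUE(trim_cluster_n),
                 adapter = adapter),
            class = "trim_policy")
}

# clip the earliest >= 8 bp exact match between a read suffix and the
# adapter prefix (3' adapter read-through)
clip_adapter <- function(seq, qual, adapter) {
  probe <- substr(adapter, 1L, 8L)
  for (i in seq_along(seq)) {
    at <- regexpr(probe, seq[i], fixed = TRUE)
    while (at > 0L) {
      tail_len <- nchar(seq[i]) - at + 1L
      if (substr(seq[i], at, nchar(seq[i])) ==
          substr(adapter, 1L, tail_len)) {
        seq[i] <- substr(seq[i], 1L, at - 1L)
        qual[i] <- substr(qual[i], 1L, at - 1L)
        break
      }
      nxt <- regexpr(probe, substr(seq[i], at + 1L, nchar(seq[i])),
                     fixed = TRUE)
      at <- if (nxt > 0L) at + nxt else -1L
    }
  }
  list(seq = seq, qual = qual)
}

#' Paired-end overlap merging policy
#'
#' @param min_overlap minimum overlap in bp (default 8).
#' @param max_diff maximum mismatch fraction in the overlap (default 0.10).
#' @export
merge_policy <- function(min_overlap = 8L, max_diff = 0.10) {
  stopifnot(min_overlap >= 1L, max_diff >= 0, max_diff <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_diff = as.numeric(max_diff)),
            class = "merge_policy")
}

#' Trim reads by quality
#'
#' @param x a sequence set with qualities.
#' @param policy a [trim_policy()].
#' @return A list with `reads` (the surviving trimmed records) and `keep`
#'   (logical over the input).
#' @export
trim_reads <- function(x, policy = trim_policy()) {
  validate_seq_set(x)
  if (any(is.na(x$qual)))
    stop("quality trimming is undefined for reads without qualities")
  if (nrow(x) == 0)
    return(list(reads = x, keep = logical(0)))
  if (!is.null(policy$adapter)) {
    cl <- clip_adapter(x$seq, x$qual, policy$adapter)
    x$seq <- cl$seq
    x$qual <- cl$qual
  }
  tr <- cpp_trim_reads(x$seq, x$qual, policy$min_phred, policy$min_len,
                       policy$trim_cluster_n)
  out <- x
  out$seq <- tr$seq
  out$qual <- tr$qual
  list(reads = out[tr$keep, , drop = FALSE], keep = tr$keep)
}

#' @rdname trim_reads
#' @param r a single-row sequence set.
#' @return `trim_read` returns the trimmed record, or `NULL` when rejected.
#' @export
trim_read <- function(r, policy = trim_policy()) {
  res <- trim_reads(r, policy)
  if (nrow(res$reads) == 0) NULL else res$reads
}

#' Filter read pairs
#'
#' Both mates are trimmed; a pair is kept only when both mates survive.
#' Reads whose mate was rejected (orphans) are counted and discarded.
#'
#' @param r1,r2 mate sequence sets aligned by record order.
#' @param policy a [trim_policy()].
#' @return A list with the kept trimmed `r1`/`r2`, the `orphans` count and
#'   the number of input pairs `n_in`.
#' @export
filter_pairs <- function(r1, r2, policy = trim_policy()) {
  if (nrow(r1) != nrow(r2))
    stop("mate files differ in record count")
  id1 <- strip_mate_suffix(r1$id)
  id2 <- strip_mate_suffix(r2$id)
  bad <- which(id1 != id2)
  if (length(bad))
    stop("pairing error at record ", bad[1], ": '", r1$id[bad[1]],
         "' vs '", r2$id[bad[1]], "'")
  if (nrow(r1) == 0)
    return(list(r1 = r1, r2 = r2, orphans = 0L, n_in = 0L, n_kept = 0L))
  if (any(is.na(r1$qual)) || any(is.na(r2$qual)))
    stop("quality trimming is undefined for reads without qualities")
  if (!is.null(policy$adapter)) {
    c1 <- clip_adapter(r1$seq, r1$qual, policy$adapter)
    r1$seq <- c1$seq; r1$qual <- c1$qual
    c2 <- clip_adapter(r2$seq, r2$qual, policy$adapter)
    r2$seq <- c2$seq; r2$qual <- c2$qual
  }
  tr1 <- cpp_trim_reads(r1$seq, r1$qual, policy$min_phred, policy$min_len,
                        policy$trim_cluster_n)
  tr2 <- cpp_trim_reads(r2$seq, r2$qual, policy$min_phred, policy$min_len,
                        policy$trim_cluster_n)
  full1 <- r1; full2 <- r2
  full1$seq <- tr1$seq; full1$qual <- tr1$qual
  full2$seq <- tr2$seq; full2$qual <- tr2$qual
  both <- tr1$keep & tr2$keep
  list(r1 = full1[both, , drop = FALSE],
       r2 = full2[both, , drop = FALSE],
       orphans = sum(xor(tr1$keep, tr2$keep)),
       n_in = nrow(r1), n_kept = sum(both))
}

per_position_max_qual <- function(quals) {
  if (length(quals) == 1L) return(quals[[1]])
  ints <- lapply(quals, function(q) as.integer(charToRaw(q)))
  rawToChar(as.raw(Reduce(pmax, ints)))
}

#' Collapse identical reads
#'
#' One record is kept per distinct sequence string; its `copies` tag is the
#' total multiplicity (sum of member copy counts), its id the first-seen
#' member id and its quality the per-position maximum over members. Output
#' is sorted by copies descending, then id.
#'
#' @param x a sequence set.
#' @export
collapse_identical <- function(x) {
  validate_seq_set(x)
  if (nrow(x) == 0) return(x)
  grp <- match(x$seq, unique(x$seq))
  first <- which(!duplicated(grp))
  copies <- as.integer(rowsum(as.numeric(x$copies), grp)[as.character(seq_len(max(grp))), 1])
  out <- x[first, , drop = FALSE]
  out$copies <- copies
  multi <- which(tabulate(grp) > 1L & !is.na(out$qual[seq_along(copies)]))
  for (g in multi)
    out$qual[g] <- per_position_max_qual(x$qual[grp == g])
  ord <- order(-out$copies, out$id)
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}

#' Collapse identical read pairs
#'
#' Pair-aware variant of [collapse_identical()]: pairs are collapsed on the
#' concatenation of both mate sequences so that mate files stay synchronized.
#'
#' @param r1,r2 mate sequence sets aligned by record order.
#' @export
collapse_pairs <- function(r1, r2) {
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  if (nrow(r1) == 0) return(list(r1 = r1, r2 = r2))
  key <- paste(r1$seq, r2$seq, sep = "~")
  grp <- match(key, unique(key))
  first <- which(!duplicated(grp))
  copies <- as.integer(rowsum(as.numeric(r1$copies), grp)[as.character(seq_len(max(grp))), 1])
  o1 <- r1[first, , drop = FALSE]
  o2 <- r2[first, , drop = FALSE]
  o1$copies <- copies
  o2$copies <- copies
  multi <- which(tabulate(grp) > 1L)
  for (g in multi) {
    if (!is.na(o1$qual[g])) o1$qual[g] <- per_position_max_qual(r1$qual[grp == g])
    if (!is.na(o2$qual[g])) o2$qual[g] <- per_position_max_qual(r2$qual[grp == g])
  }
  ord <- order(-o1$copies, o1$id)
  rownames(o1) <- rownames(o2) <- NULL
  list(r1 = o1[ord, , drop = FALSE], r2 = o2[ord, , drop = FALSE])
}

#' Merge overlapping read pairs
#'
#' The reverse mate is reverse-complemented and all overlap offsets are
#' scanned; overlaps of at least `min_overlap` bp with a mismatch fraction
#' at most `max_diff` are candidates, and the longest one wins (ties: fewest
#' mismatches, then smallest offset). In the overlapped region the
#' higher-quality base is emitted with the maximum of the two qualities.
#'
#' @param r1,r2 mate sequence sets aligned by record order.
#' @param policy a [merge_policy()].
#' @return A list with `merged` (a sequence set of merged reads),
#'   `unmerged1`/`unmerged2`, and a logical `was_merged` over input pairs.
#' @export
merge_pairs <- function(r1, r2, policy = merge_policy()) {
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  if (nrow(r1) == 0)
    return(list(merged = r1, unmerged1 = r1, unmerged2 = r2,
                was_merged = logical(0)))
  q1 <- ifelse(is.na(r1$qual), strrep("I", nchar(r1$seq)), r1$qual)
  q2 <- ifelse(is.na(r2$qual), strrep("I", nchar(r2$seq)), r2$qual)
  res <- cpp_merge_pairs(r1$seq, q1, r2$seq, q2,
                         policy$min_overlap, policy$max_diff)
  ok <- res$merged
  merged <- seq_set(strip_mate_suffix(r1$id[ok]), res$seq[ok],
                    res$qual[ok], r1$copies[ok], r1$csize[ok])
  list(merged = merged,
       unmerged1 = r1[!ok, , drop = FALSE],
       unmerged2 = r2[!ok, , drop = FALSE],
       was_merged = ok,
       offset = res$offset[ok], overlap = res$overlap[ok],
       mismatches = res$mismatches[ok])
}

#' @rdname merge_pairs
#' @export
merge_pair <- function(r1, r2, policy = merge_policy()) {
  res <- merge_pairs(r1, r2, policy)
  if (nrow(res$merged) == 0) NULL else res$merged
}
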