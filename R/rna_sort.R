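#' rRNA/tRNA read sorting
#'
#' Reads are classified into rRNA/tRNA categories against user-supplied
#' reference sets by canonical k-mer containment: for each category the
#' fraction of a read's k-mers found in that category's reference index is
#' computed, and the read is assigned the best category when its fraction
#' reaches `min_frac`, otherwise it is left as potential mRNA. Ties break by
#' the fixed priority SSU > LSU > FIVE_S > TRNA. K-mers containing N are
#' skipped on both sides.
#'
#' @name rna_sort
NULL

RNA_CATEGORIES <- c("SSU", "LSU", "FIVE_S", "TRNA")

#' Build a category k-mer index
#'
#' @param refs named list of reference sequence sets (or FASTA paths), with
#'   names among `SSU`, `LSU`, `FIVE_S`, `TRNA`.
#' @param k k-mer size (8-15; default 15). Canonical form = lexicographic
#'   minimum of a k-mer and its reverse complement.
#' @export
build_kmer_index <- function(refs, k = 15L) {
  stopifnot(k >= 8L, k <= 15L)
  if (is.null(names(refs)) || !all(names(refs) %in% RNA_CATEGORIES))
    stop("reference list names must be among: ",
         paste(RNA_CATEGORIES, collapse = ", "))
  cats <- RNA_CATEGORIES[RNA_CATEGORIES %in% names(refs)]
  sets <- lapply(cats, function(cat) {
    r <- refs[[cat]]
    if (is.character(r)) r <- read_fasta(r)
    if (nrow(r) == 0)
      stop("empty reference set for category '", cat, "'")
    cpp_kmer_set(r$seq, as.integer(k))
  })
  names(sets) <- cats
  structure(list(k = as.integer(k), sets = sets), class = "kmer_index")
}

#' Classify reads against a k-mer index
#'
#' @param x a sequence set.
#' @param idx a [build_kmer_index()] result.
#' @param min_frac minimum shared k-mer fraction for an rRNA/tRNA call
#'   (default 0.25); reads below it are labelled `MRNA`.
#' @return A factor over `c(names(idx$sets), "MRNA")`; reads shorter than k
#'   are classified `MRNA` with a warning.
#' @export
classify_reads <- function(x, idx, min_frac = 0.25) {
  stopifnot(inherits(idx, "kmer_index"))
  seqs <- if (is.data.frame(x)) x$seq else as.character(x)
  if (any(nchar(seqs) < idx$k))
    warning(sum(nchar(seqs) < idx$k),
            " read(s) shorter than k = ", idx$k, " classified as MRNA")
  res <- cpp_classify_reads(seqs, idx$sets, idx$k, min_frac)
  lev <- c(names(idx$sets), "MRNA")
  cat <- ifelse(res$category == 0L, length(lev), res$category)
  structure(factor(lev[cat], levels = c(RNA_CATEGORIES, "MRNA")),
            fractions = {
              f <- res$fractions
              rownames(f) <- names(idx$sets)
              f
            })
}

#' @rdname classify_reads
#' @export
classify_read <- function(x, idx, min_frac = 0.25) {
  as.character(classify_reads(x, idx, min_frac))[1]
}

#' Sort read pairs into rRNA/tRNA/mRNA buckets
#'
#' A pair is assigned the highest-priority non-MRNA category of either mate;
#' pairs with both mates unclassified go to the `MRNA` bucket. Every input
#' pair lands in exactly one bucket.
#'
#' @param r1,r2 mate sequence sets aligned by record order.
#' @param idx a [build_kmer_index()] result.
#' @param min_frac see [classify_reads()].
#' @return A named list of `list(r1, r2)` buckets, one per category present
#'   in the index plus `MRNA`.
#' @export
sort_pairs <- function(r1, r2, idx, min_frac = 0.25) {
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  lev <- c(RNA_CATEGORIES, "MRNA")
  c1 <- as.integer(classify_reads(r1, idx, min_frac))
  c2 <- as.integer(classify_reads(r2, idx, min_frac))
  pair_cat <- pmin(c1, c2)   # smaller index = higher priority; MRNA is last
  out <- lapply(c(names(idx$sets), "MRNA"), function(cat) {
    sel <- pair_cat == match(cat, lev)
    list(r1 = r1[sel, , drop = FALSE], r2 = r2[sel, , drop = FALSE])
  })
  names(out) <- c(names(idx$sets), "MRNA")
  out
}
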