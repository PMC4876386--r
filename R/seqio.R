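#' Sequence sets
#'
#' The package's working container for reads and reference sequences is a
#' plain data frame with columns `id` (token, no whitespace), `seq` (DNA over
#' A/C/G/T/N), `qual` (Phred+33 string of the same length, or `NA` for
#' FASTA-derived records), and the integer header tags `copies` (multiplicity
#' of a collapsed read) and `csize` (total weight of the cluster a
#' representative stands for). Missing tags default to 1.
#'
#' @param id character vector of record identifiers (no whitespace).
#' @param seq character vector of DNA sequences.
#' @param qual character vector of Phred+33 quality strings, or `NA`.
#' @param copies,csize integer tag vectors (default 1).
#' @return A `data.frame` with columns `id`, `seq`, `qual`, `copies`, `csize`.
#' @export
seq_set <- function(id, seq, qual = NA_character_, copies = 1L, csize = 1L) {
  n <- length(seq)
  x <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                  qual = rep_len(as.character(qual), n),
                  copies = rep_len(as.integer(copies), n),
                  csize = rep_len(as.integer(csize), n),
                  stringsAsFactors = FALSE)
  validate_seq_set(x)
  x
}

validate_seq_set <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("id", "seq", "qual", "copies", "csize") %in% names(x)))
  if (any(grepl("[[:space:]]", x$id)))
    stop("sequence ids must not contain whitespace")
  if (any(grepl("[^ACGTN]", x$seq)))
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  has_q <- !is.na(x$qual)
  if (any(nchar(x$qual[has_q]) != nchar(x$seq[has_q])))
    stop("quality strings must have the same length as their sequences")
  if (any(x$copies < 1L) || any(x$csize < 1L))
    stop("'copies' and 'csize' tags must be >= 1")
  invisible(x)
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual character vector of Phred+33 strings.
#' @param phred list or vector of integer Phred scores (0-41).
#' @return `phred_decode` returns a list of integer vectors; `phred_encode`
#'   the corresponding Phred+33 strings.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer(0))
    as.integer(charToRaw(q)) - 33L
  })
}

#' @rdname phred_decode
#' @export
phred_encode <- function(phred) {
  if (!is.list(phred)) phred <- list(phred)
  vapply(phred, function(p) {
    if (any(p < 0L | p > 41L)) stop("Phred scores must lie in [0, 41]")
    rawToChar(as.raw(p + 33L))
  }, character(1))
}

#' Parse and format header tags
#'
#' Header tags follow the grammar `id`, `id|copies=N` or
#' `id|copies=N|csize=M`; missing tags default to 1. `format_tags` omits tags
#' equal to 1, so `parse_tags(format_tags(...))` is the identity on tag maps.
#'
#' @param header character vector of header tokens.
#' @return A data frame with columns `id`, `copies`, `csize`.
#' @export
parse_tags <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)
  id <- vapply(parts, `[[`, character(1), 1L)
  copies <- rep(1L, length(header))
  csize <- rep(1L, length(header))
  for (i in seq_along(parts)) {
    for (tag in parts[[i]][-1]) {
      kv <- strsplit(tag, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L || !kv[1] %in% c("copies", "csize"))
        stop("malformed header tag: '", tag, "'")
      val <- suppressWarnings(as.integer(kv[2]))
      if (is.na(val) || val < 1L || kv[2] != as.character(val))
        stop("header tag '", kv[1], "' must be a positive integer, got '",
             kv[2], "'")
      if (kv[1] == "copies") copies[i] <- val else csize[i] <- val
    }
  }
  data.frame(id = id, copies = copies, csize = csize,
             stringsAsFactors = FALSE)
}

#' @rdname parse_tags
#' @param id,copies,csize fields to format.
#' @export
format_tags <- function(id, copies = 1L, csize = 1L) {
  out <- id
  out <- ifelse(copies != 1L, paste0(out, "|copies=", copies), out)
  out <- ifelse(csize != 1L, paste0(out, "|csize=", csize), out)
  out
}

#' Read and write FASTQ with header tags
#'
#' FASTQ records are the usual 4-line blocks with Phred+33 qualities capped
#' at 41 (HiSeq range); higher encodings are rejected. Copy-count and
#' cluster-size annotations are carried in the header as `|copies=N|csize=M`
#' and round-trip bit-exactly.
#'
#' @param path file path.
#' @return A sequence set (see [seq_set()]).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(seq_set(character(0), character(0), character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": missing '+' separator line")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1],
         ": sequence and quality lengths differ")
  qr <- lapply(qual, charToRaw)
  bad <- which(vapply(qr, function(r) any(r < as.raw(33L) | r > as.raw(74L)),
                      logical(1)))
  if (length(bad))
    stop("FASTQ record ", bad[1],
         ": quality character outside the Phred+33 range [0, 41]")
  token <- sub("[[:space:]].*$", "", substring(hdr, 2L))
  tags <- parse_tags(token)
  seq_set(tags$id, seq, qual, tags$copies, tags$csize)
}

#' @rdname read_fastq
#' @param x a sequence set with qualities.
#' @export
write_fastq <- function(x, path) {
  validate_seq_set(x)
  if (any(is.na(x$qual)))
    stop("cannot write FASTQ for records without qualities")
  hdr <- paste0("@", format_tags(x$id, x$copies, x$csize))
  writeLines(rbind(hdr, x$seq, "+", x$qual), path)
  invisible(path)
}

#' Read and write FASTA (via Biostrings)
#'
#' @param path file path.
#' @return A sequence set with `qual = NA`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  token <- sub("[[:space:]].*$", "", names(ss))
  tags <- parse_tags(token)
  seq_set(tags$id, as.character(ss), NA_character_, tags$copies, tags$csize)
}

#' @rdname read_fasta
#' @param x a sequence set.
#' @export
write_fasta <- function(x, path) {
  validate_seq_set(x)
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- format_tags(x$id, x$copies, x$csize)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Abundance matrices
#'
#' Feature-by-sample matrices of non-negative counts, the interchange object
#' between the pipeline and the statistics layer. Stored as a base matrix
#' with feature ids as row names and sample names as column names; written
#' as TSV with a leading `feature` column.
#'
#' @param m a numeric matrix with unique row and column names and
#'   non-negative entries.
#' @export
validate_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    stop("abundance matrix must have unique sample names")
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    stop("abundance matrix must have unique feature ids")
  if (any(m < 0)) stop("abundance matrix entries must be >= 0")
  invisible(m)
}

#' @rdname validate_matrix
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  validate_matrix(m)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(m) == 0)
    df <- data.frame(matrix(nrow = 0, ncol = ncol(m) + 1,
                            dimnames = list(NULL, c("feature", colnames(m)))),
                     check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname validate_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature
  validate_matrix(m)
  m
}

#' Read a gene annotation map
#'
#' TSV with header `gene_id og_id ko_id category` linking catalog genes to
#' orthologous-group ids, KO ids and one-letter functional categories; empty
#' fields mean unannotated.
#'
#' @param path file path.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  need <- c("gene_id", "og_id", "ko_id", "category")
  if (!all(need %in% names(df)))
    stop("annotation map must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Strip paired-end mate suffixes from read ids
#'
#' Removes trailing `/1`, `/2` mate markers (CASAVA 1.8 `1:N:...` comments
#' are already dropped with the whitespace split at parse time).
#'
#' @param id character vector of read ids.
#' @export
strip_mate_suffix <- function(id) sub("/[12]$", "", id)
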