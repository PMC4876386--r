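#' Synthetic gene catalogs
#'
#' Generates per-organism sets of protein-coding-like genes: lengths drawn
#' uniformly from `len_range` (rounded to whole codons) and sequences built
#' from random non-stop codons, so every gene is stop-free in its own
#' frame, as a coding sequence is.
#'
#' @param n_organisms number of organisms (default 5).
#' @param genes_per_org genes generated per organism.
#' @param len_range gene length range in nt (default 300-1500).
#' @param seed optional integer seed.
#' @return A data frame with `org`, `gene_id`, `seq`.
#' @export
synth_gene_catalog <- function(n_organisms = 5L, genes_per_org = 1000L,
                               len_range = c(300L, 1500L), seed = NULL) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  run <- function() {
    n <- n_organisms * genes_per_org
    len <- 3L * (sample(len_range[1]:len_range[2], n, replace = TRUE) %/% 3L)
    seqs <- vapply(len, function(L)
      paste(sample(codons, L %/% 3L, replace = TRUE), collapse = ""),
      character(1))
    data.frame(org = rep(paste0("org", seq_len(n_organisms)),
                         each = genes_per_org),
               gene_id = sprintf("org%d_g%04d",
                                 rep(seq_len(n_organisms), each = genes_per_org),
                                 rep(seq_len(genes_per_org), n_organisms)),
               seq = seqs, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Draw a mock community from source genes
#'
#' Selects exactly `genes_per_org` genes per organism, randomly without
#' replacement.
#'
#' @param source_genes a data frame with `org`, `gene_id`, `seq`.
#' @param genes_per_org genes drawn per organism (default 1000).
#' @param seed optional integer seed.
#' @export
build_mock <- function(source_genes, genes_per_org = 1000L, seed = NULL) {
  stopifnot(all(c("org", "gene_id", "seq") %in% names(source_genes)))
  run <- function() {
    picks <- lapply(split(seq_len(nrow(source_genes)), source_genes$org),
                    function(rows) {
                      if (length(rows) < genes_per_org)
                        stop("organism '", source_genes$org[rows[1]],
                             "' supplies only ", length(rows),
                             " genes (need ", genes_per_org, ")")
                      sort(sample(rows, genes_per_org))
                    })
    out <- source_genes[unlist(picks), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Assign a differential-expression design
#'
#' Exactly `round(frac_up * G)` genes are labelled UP (fold-change `fold`
#' in group 2) and `round(frac_down * G)` DOWN (fold-change `1/fold`); the
#' rest are NULL.
#'
#' @param genes a data frame with `gene_id` and `seq`.
#' @param frac_up,frac_down fractions of DE genes (default 0.20 each).
#' @param fold fold-change multiplier (default 4).
#' @param seed optional integer seed.
#' @return A `mock_design` list with the labelled gene table and parameters.
#' @export
assign_de <- function(genes, frac_up = 0.20, frac_down = 0.20, fold = 4,
                      seed = NULL) {
  stopifnot(frac_up + frac_down <= 1)
  G <- nrow(genes)
  n_up <- round(frac_up * G)
  n_down <- round(frac_down * G)
  run <- function() {
    lab <- rep("NULL", G)
    de <- sample(G, n_up + n_down)
    lab[de[seq_len(n_up)]] <- "UP"
    if (n_down > 0) lab[de[n_up + seq_len(n_down)]] <- "DOWN"
    lab
  }
  label <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  genes$label <- label
  genes$fc <- ifelse(label == "UP", fold, ifelse(label == "DOWN", 1 / fold, 1))
  structure(list(genes = genes, fold = fold, frac_up = frac_up,
                 frac_down = frac_down),
            class = "mock_design")
}

#' Simulate negative-binomial truth counts
#'
#' Per gene and sample, counts are drawn from a negative binomial with mean
#' `mu_g * fc_g` in group 2 (`mu_g` proportional to `baseline_mean` times
#' gene length) and dispersion `phi` (`variance = mu + phi mu^2`);
#' `dispersion = 0` gives Poisson counts.
#'
#' @param design a [assign_de()] result.
#' @param n1,n2 samples per group (default 10 each).
#' @param baseline_mean mean read pairs per average-length gene (default 20).
#' @param dispersion NB dispersion `phi` (default 0.2).
#' @param seed optional integer seed.
#' @return A gene x sample count matrix with a `groups` attribute.
#' @export
simulate_counts <- function(design, n1 = 10L, n2 = 10L, baseline_mean = 20,
                            dispersion = 0.2, seed = NULL) {
  stopifnot(inherits(design, "mock_design"))
  g <- design$genes
  len <- nchar(g$seq)
  mu <- baseline_mean * len / mean(len)
  samples <- c(paste0("g1_s", seq_len(n1)), paste0("g2_s", seq_len(n2)))
  group <- rep(c(1L, 2L), c(n1, n2))
  run <- function() {
    m <- matrix(0L, nrow = nrow(g), ncol = n1 + n2,
                dimnames = list(g$gene_id, samples))
    for (s in seq_len(n1 + n2)) {
      mus <- if (group[s] == 2L) mu * g$fc else mu
      m[, s] <- if (dispersion > 0)
        rnbinom(nrow(g), mu = mus, size = 1 / dispersion)
      else rpois(nrow(g), mus)
    }
    m
  }
  m <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(m, "groups") <- group
  m
}

#' Quality models
#'
#' An empirical per-position Phred histogram trained from a FASTQ file (all
#' reads must share one length), or a flat model emitting a constant score.
#'
#' @param x a sequence set with qualities, or a FASTQ path.
#' @export
train_quality_model <- function(x) {
  if (is.character(x)) x <- read_fastq(x)
  if (nrow(x) == 0) stop("cannot train a quality model from an empty file")
  if (any(is.na(x$qual))) stop("quality model training requires qualities")
  L <- unique(nchar(x$qual))
  if (length(L) != 1)
    stop("mixed read lengths (", paste(L, collapse = ", "),
         "); the quality model requires uniform length")
  q <- matrix(unlist(phred_decode(x$qual)), nrow = L)
  counts <- vapply(seq_len(L), function(p) tabulate(q[p, ] + 1L, 42L),
                   integer(42))
  structure(list(counts = counts, qvals = 0:41, read_len = L),
            class = "quality_model")
}

#' @rdname train_quality_model
#' @param read_len read length of the model.
#' @param phred the constant Phred score emitted (default 30).
#' @export
flat_quality_model <- function(read_len = 76L, phred = 30L) {
  counts <- matrix(0L, nrow = 42, ncol = read_len)
  counts[phred + 1L, ] <- 1L
  structure(list(counts = counts, qvals = 0:41, read_len = read_len),
            class = "quality_model")
}

#' Sample quality strings from a model
#'
#' @param qm a quality model.
#' @param n number of quality strings to draw (uses the R RNG).
#' @export
sample_quals <- function(qm, n) {
  stopifnot(inherits(qm, "quality_model"))
  probs <- sweep(qm$counts, 2, colSums(qm$counts), "/")
  cum <- apply(probs, 2, cumsum)
  cpp_sample_quals(cum, qm$qvals, as.integer(n))
}

#' Simulate paired-end reads from truth counts
#'
#' For each truth count a fragment of truncated-normal length (clipped to
#' `[read_len, gene length]`) is placed uniformly on the gene; mate 1 reads
#' its 5' end and mate 2 is the reverse complement of its 3' end. Per-base
#' qualities come from the quality model and each base is substituted with
#' its Phred error probability.
#'
#' @param design a [assign_de()] result.
#' @param counts a truth count matrix from [simulate_counts()].
#' @param qm a quality model.
#' @param read_len read length (default 76).
#' @param frag_mean,frag_sd fragment length distribution (default 250 +- 25).
#' @param seed optional integer seed.
#' @return A named list (per sample) of `list(r1, r2)` sequence sets; genes
#'   shorter than `read_len` are skipped with a warning.
#' @export
simulate_reads <- function(design, counts, qm, read_len = 76L,
                           frag_mean = 250, frag_sd = 25, seed = NULL) {
  stopifnot(inherits(design, "mock_design"))
  g <- design$genes
  len <- nchar(g$seq)
  short <- len < read_len
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than the read length skipped")
    counts[short, ] <- 0L
  }
  run <- function() {
    out <- vector("list", ncol(counts))
    names(out) <- colnames(counts)
    for (s in seq_len(ncol(counts))) {
      cnt <- counts[, s]
      gi <- rep(seq_len(nrow(counts)), cnt)
      n <- length(gi)
      if (n == 0) {
        empty <- seq_set(character(0), character(0), character(0))
        out[[s]] <- list(r1 = empty, r2 = empty)
        next
      }
      glen <- len[gi]
      flen <- pmin(pmax(round(rnorm(n, frag_mean, frag_sd)), read_len), glen)
      start <- floor(runif(n) * (glen - flen + 1)) + 1L
      frag_end <- start + flen - 1L
      s1 <- substring(g$seq[gi], start, start + read_len - 1L)
      s2 <- cpp_revcomp(substring(g$seq[gi], frag_end - read_len + 1L,
                                  frag_end))
      q1 <- sample_quals(qm, n)
      q2 <- sample_quals(qm, n)
      ids <- sprintf("%s_r%06d", colnames(counts)[s], seq_len(n))
      out[[s]] <- list(
        r1 = seq_set(ids, cpp_apply_errors(s1, q1), q1),
        r2 = seq_set(ids, cpp_apply_errors(s2, q2), q2))
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Remove catalog entries resembling source genes
#'
#' Catalog entries aligning to any source sequence at more than `max_id`
#' percent identity over at least 80% of the shorter sequence are removed,
#' preventing accuracy overestimates from near-identical references. The
#' operation is idempotent.
#'
#' @param catalog a sequence set of catalog entries.
#' @param sources a sequence set of source genes.
#' @param max_id identity ceiling in percent (default 90).
#' @return The filtered catalog; the number of removals is reported in a
#'   message.
#' @export
decontaminate_reference <- function(catalog, sources, max_id = 90) {
  if (nrow(catalog) == 0 || nrow(sources) == 0) return(catalog)
  res <- cpp_map_best_hit(catalog$seq, sources$seq, max_id, 0.80, 15L,
                          TRUE, TRUE)
  drop <- res$target > 0L & !is.na(res$identity) &
    res$identity > max_id + 1e-9
  message(sum(drop), " catalog entr(ies) removed at > ", max_id,
          "% identity to a source gene")
  catalog[!drop, , drop = FALSE]
}

#' Synthetic lineage-labelled 16S community
#'
#' Builds a hierarchy of 16S-like reference sequences: a random root per
#' phylum, with classes, orders, families, genera and species derived by
#' successive substitution mutations at decreasing per-level rates, so that
#' sequence divergence mirrors taxonomic distance. Each leaf (organism) gets
#' a unique 7-rank Greengenes-style lineage.
#'
#' @param n_organisms number of leaf organisms (default 200).
#' @param seq_len 16S-like sequence length (default 1200).
#' @param n_phyla number of phyla (default 4).
#' @param rates substitution rates per level class..species.
#' @param seed optional integer seed.
#' @return A data frame shaped like [read_16s_reference()] output.
#' @export
synth_16s_community <- function(n_organisms = 200L, seq_len = 1200L,
                                n_phyla = 4L,
                                rates = c(0.10, 0.07, 0.05, 0.04, 0.03),
                                seed = NULL) {
  run <- function() {
    mutate <- function(s, rate) {
      v <- strsplit(s, "")[[1]]
      hit <- runif(length(v)) < rate
      if (any(hit)) {
        sub <- vapply(v[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        v[hit] <- sub
      }
      paste(v, collapse = "")
    }
    # branching factors: phyla x 2 x 2 x 2 x 2 x species-per-genus
    per_genus <- ceiling(n_organisms / (n_phyla * 16))
    nodes <- list()
    orgs <- data.frame(id = character(0), seq = character(0),
                       lineage = character(0), stringsAsFactors = FALSE)
    count <- 0L
    for (p in seq_len(n_phyla)) {
      pseq <- paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
                    collapse = "")
      for (cl in 1:2) {
        cseq <- mutate(pseq, rates[1])
        for (o in 1:2) {
          oseq <- mutate(cseq, rates[2])
          for (f in 1:2) {
            fseq <- mutate(oseq, rates[3])
            for (ge in 1:2) {
              gseq <- mutate(fseq, rates[4])
              for (sp in seq_len(per_genus)) {
                if (count >= n_organisms) break
                count <- count + 1L
                sseq <- mutate(gseq, rates[5])
                tag <- sprintf("P%dC%dO%dF%dG%d", p, cl, o, f, ge)
                lin <- paste0("k__Bacteria; p__P", p,
                              "; c__", tag_part(tag, 2),
                              "; o__", tag_part(tag, 3),
                              "; f__", tag_part(tag, 4),
                              "; g__", tag,
                              "; s__org", sprintf("%04d", count))
                orgs <- rbind(orgs, data.frame(
                  id = sprintf("org%04d", count), seq = sseq, lineage = lin,
                  stringsAsFactors = FALSE))
              }
            }
          }
        }
      }
    }
    orgs
  }
  orgs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ranks <- parse_lineage(orgs$lineage)
  cbind(orgs, as.data.frame(ranks, stringsAsFactors = FALSE))
}

tag_part <- function(tag, levels) {
  # P1C2O1F2G1 -> prefix covering the first `levels` components
  m <- regmatches(tag, gregexpr("[A-Z][0-9]+", tag))[[1]]
  paste(m[seq_len(levels)], collapse = "")
}
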