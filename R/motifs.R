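# Local k-mer motif machinery for GLIPH-style specificity grouping.

trim_core <- function(cdr3, trim) {
  n <- nchar(cdr3)
  core_len <- n - trim[1] - trim[2]
  out <- rep("", length(cdr3))
  ok <- core_len >= 1L
  out[ok] <- substr(cdr3[ok], trim[1] + 1L, n[ok] - trim[2])
  out
}

check_aa <- function(cdr3) {
  bad <- !grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), cdr3)
  if (any(bad))
    stop_tcrdrive("validation_error",
                  "non-amino-acid character in CDR3(s): %s",
                  paste(utils::head(cdr3[bad], 5L), collapse = ", "))
}

kmers_of <- function(core, k) {
  n <- nchar(core)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  substring(core, starts, starts + k - 1L)
}

#' Extract local CDR3 motifs
#'
#' All contiguous k-mers (k from `motif_lengths`, default {3,4}) of the
#' CDR3 core, i.e. the sequence with the first `cdr3_trim[1]` (default 3)
#' and last `cdr3_trim[2]` (default 2) residues removed. The trim excludes
#' the conserved germline-encoded ends of the junction so motifs come from
#' the antigen-contacting centre. CDR3s whose core is shorter than the
#' smallest k yield an empty set rather than an error.
#'
#' @param cdr3_aa A single CDR3 amino-acid string.
#' @param config A [pipeline_config()].
#' @return Character vector of motifs (duplicates possible when a k-mer
#'   repeats within the core).
#' @export
extract_local_motifs <- function(cdr3_aa, config = NULL) {
  config <- as_config(config)
  stopifnot(length(cdr3_aa) == 1L)
  check_aa(cdr3_aa)
  core <- trim_core(cdr3_aa, config$cdr3_trim)
  if (nchar(core) == 0L) return(character())
  unlist(lapply(config$motif_lengths, function(k) kmers_of(core, k)),
         use.names = FALSE)
}

# Motif -> number of distinct CDR3s containing it (presence/absence per
# distinct CDR3, not per read, so large clones cannot dominate enrichment).
motif_support_table <- function(cdr3s, config) {
  cdr3s <- unique(cdr3s)
  cores <- trim_core(cdr3s, config$cdr3_trim)
  keep <- nchar(cores) > 0L
  cores <- cores[keep]
  per <- lapply(cores, function(core) {
    unique(unlist(lapply(config$motif_lengths, function(k) kmers_of(core, k)),
                  use.names = FALSE))
  })
  motifs <- unlist(per, use.names = FALSE)
  if (length(motifs) == 0L)
    return(list(counts = integer(), members = list(),
                n_total = length(cdr3s), cdr3 = cdr3s[keep]))
  id <- rep.int(seq_along(per), lengths(per))
  counts <- table(motifs)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       motif = motifs, cdr3_id = id,
       n_total = length(cdr3s), cdr3 = cdr3s[keep])
}

#' Prepare a reference repertoire for repeated enrichment testing
#'
#' Pre-computes the motif support table and length-grouped CDR3 cores of a
#' reference repertoire so that many samples can be tested against the
#' same background without recounting it.
#'
#' @param reference A `tcr_repertoire` (or character vector of CDR3s) with
#'   at least 100 distinct CDR3s.
#' @param config A [pipeline_config()].
#' @return An object of class `tcrdrive_reference_index`.
#' @export
index_reference <- function(reference, config = NULL) {
  config <- as_config(config)
  cdr3s <- if (inherits(reference, "tcr_repertoire"))
    reference$clonotypes$cdr3_aa else as.character(reference)
  cdr3s <- unique(cdr3s)
  if (length(cdr3s) < 100L)
    stop_tcrdrive("parameter_error",
                  "reference must contain >= 100 distinct CDR3s (got %d): enrichment against a tiny background is vacuous",
                  length(cdr3s))
  check_aa(cdr3s)
  tab <- motif_support_table(cdr3s, config)
  cores <- trim_core(cdr3s, config$cdr3_trim)
  cores <- cores[nchar(cores) > 0L]
  structure(list(motif_counts = tab$counts,
                 n_total = tab$n_total,
                 cores_by_length = split(cores, nchar(cores)),
                 config_trim = config$cdr3_trim,
                 config_k = config$motif_lengths),
            class = "tcrdrive_reference_index")
}

as_reference_index <- function(reference, config) {
  if (inherits(reference, "tcrdrive_reference_index")) return(reference)
  index_reference(reference, config)
}

# One-sided (greater) Fisher exact p for tables [(a, A-a), (b, B-b)]:
# hypergeometric tail P(X >= a) with X ~ Hyper(total = A+B, marked = a+b,
# drawn = A). Vectorised over a, b.
fisher_greater_p <- function(a, A, b, B) {
  stats::phyper(a - 1, a + b, (A - a) + (B - b), A, lower.tail = FALSE)
}

#' Motif enrichment against a reference repertoire
#'
#' For every local motif present in at least two distinct sample CDR3s,
#' tests whether the motif is over-represented among the sample's distinct
#' CDR3s relative to the reference repertoire, with a one-sided (greater)
#' Fisher exact test on the 2x2 table
#' `[(n_sample, n_sample_total - n_sample), (n_ref, n_ref_total - n_ref)]`.
#' A motif is flagged enriched when `p < enrichment_alpha` and its fold
#' enrichment `(n_sample/n_sample_total) / (n_ref/n_ref_total)` is at
#' least `min_fold`. When a motif never occurs in the reference the fold
#' is reported with a Haldane-style smoothed denominator
#' (`n_ref := 0.5`); the test itself always uses the raw table.
#'
#' @param sample A `tcr_repertoire` (or character vector of CDR3s).
#' @param reference A `tcr_repertoire`, CDR3 vector, or a pre-built
#'   [index_reference()] object with >= 100 distinct CDR3s.
#' @param config A [pipeline_config()].
#' @return data.frame of `MotifRecord`s: `motif`, `k`, `n_sample`,
#'   `n_sample_total`, `n_ref`, `n_ref_total`, `fold`, `p`, `enriched`.
#' @export
motif_enrichment <- function(sample, reference, config = NULL) {
  config <- as_config(config)
  cdr3s <- if (inherits(sample, "tcr_repertoire"))
    sample$clonotypes$cdr3_aa else as.character(sample)
  if (length(cdr3s) == 0L)
    stop_tcrdrive("empty_repertoire", "sample has no CDR3s")
  check_aa(cdr3s)
  ref <- as_reference_index(reference, config)

  tab <- motif_support_table(cdr3s, config)
  counts <- tab$counts
  counts <- counts[counts >= 2L]  # support floor: >= 2 distinct sample CDR3s
  if (length(counts) == 0L) {
    return(data.frame(motif = character(), k = integer(),
                      n_sample = integer(), n_sample_total = integer(),
                      n_ref = integer(), n_ref_total = integer(),
                      fold = numeric(), p = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  motif <- names(counts)
  n_sample <- as.integer(counts)
  n_sample_total <- tab$n_total
  n_ref <- ref$motif_counts[motif]
  n_ref[is.na(n_ref)] <- 0L
  n_ref <- as.integer(n_ref)
  n_ref_total <- ref$n_total

  rate_s <- n_sample / n_sample_total
  fold <- rate_s / (pmax(n_ref, 0.5) / n_ref_total)
  p <- fisher_greater_p(n_sample, n_sample_total, n_ref, n_ref_total)
  out <- data.frame(motif = motif, k = nchar(motif),
                    n_sample = n_sample, n_sample_total = n_sample_total,
                    n_ref = n_ref, n_ref_total = n_ref_total,
                    fold = fold, p = p,
                    enriched = p < config$enrichment_alpha & fold >= config$min_fold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order_stable(out$p, out$motif), , drop = FALSE]
}

#' Global near-identity links between CDR3s
#'
#' Symmetric edge set over pairs of equal-length CDR3s whose trimmed cores
#' differ at no more than `hamming_max` (default 1) positions — the
#' "global" linking rule of GLIPH-style grouping. CDR3s of different
#' lengths are never linked; self-pairs are excluded.
#'
#' @param cdr3_list Character vector of CDR3 amino-acid sequences
#'   (positions in the output index into this vector).
#' @param config A [pipeline_config()].
#' @return data.frame with columns `i`, `j` (1-based indices, `i < j`) and
#'   `distance`.
#' @export
global_pairs <- function(cdr3_list, config = NULL) {
  config <- as_config(config)
  empty <- data.frame(i = integer(), j = integer(), distance = integer())
  if (length(cdr3_list) < 2L) return(empty)
  check_aa(cdr3_list)
  cores <- trim_core(cdr3_list, config$cdr3_trim)
  # cores of equal-length CDR3s have equal length, so grouping by full
  # CDR3 length equals grouping by core length here
  lens <- nchar(cdr3_list)
  usable <- which(nchar(cores) > 0L)
  out <- list()
  for (L in unique(lens[usable])) {
    idx <- usable[lens[usable] == L]
    if (length(idx) < 2L) next
    m <- do.call(rbind, strsplit(cores[idx], ""))
    nn <- length(idx)
    # pairwise Hamming distances within the length class
    for (a in seq_len(nn - 1L)) {
      rest <- (a + 1L):nn
      d <- colSums(m[a, ] != t(m[rest, , drop = FALSE]))
      hit <- which(d <= config$hamming_max)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          i = idx[a], j = idx[rest[hit]], distance = as.integer(d[hit]))
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  swap <- res$i > res$j
  tmp <- res$i[swap]; res$i[swap] <- res$j[swap]; res$j[swap] <- tmp
  res <- res[order_stable(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Significance of a global edge: the shared trimmed-core pattern (the core
# with any mismatching position wildcarded) must pass the same enrichment
# test as a local motif: >= 2 distinct sample CDR3s matching, one-sided
# Fisher p < alpha, fold >= min_fold against the reference.
global_edge_significant <- function(core_a, core_b, sample_cores, ref, config) {
  L <- nchar(core_a)
  if (L != nchar(core_b)) return(FALSE)
  av <- strsplit(core_a, "")[[1]]
  bv <- strsplit(core_b, "")[[1]]
  pattern <- av
  pattern[av != bv] <- "."
  rx <- sprintf("^%s$", paste(pattern, collapse = ""))
  n_sample <- sum(grepl(rx, sample_cores[nchar(sample_cores) == L]))
  if (n_sample < 2L) return(FALSE)
  ref_cores <- ref$cores_by_length[[as.character(L)]] %||% character()
  n_ref <- sum(grepl(rx, ref_cores))
  n_sample_total <- length(sample_cores)
  n_ref_total <- ref$n_total
  fold <- (n_sample / n_sample_total) / (pmax(n_ref, 0.5) / n_ref_total)
  p <- fisher_greater_p(n_sample, n_sample_total, n_ref, n_ref_total)
  p < config$enrichment_alpha && fold >= config$min_fold
}
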