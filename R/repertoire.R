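#' TCR repertoire container
#'
#' A `tcr_repertoire` holds one sample's aggregated clonotypes: for each
#' clonotype a key (under the chosen key scheme), CDR3 beta amino-acid
#' sequence, optional paired alpha CDR3 and gene calls, the read count
#' (reads, templates or cells depending on platform), its frequency within
#' the repertoire, a productivity flag and an optional leukemic annotation.
#' Clonotypes are kept in a deterministic order: read count descending,
#' CDR3 amino-acid sequence ascending (byte order), so written outputs are
#' byte-stable across runs.
#'
#' @param clonotypes data.frame with at least `cdr3_aa` and `read_count`;
#'   optional columns `cdr3_aa_alpha`, `v_call`, `j_call`, `productive`,
#'   `leukemic`, `key`.
#' @param sample_id Sample identifier.
#' @param cohort_label Cohort tag (e.g. "T-LGLL", "healthy", "RA", "SKCM").
#' @param sort_label Cell-sort tag (e.g. "CD8", "MNC", "CD45").
#' @param key_scheme How clonotype keys are formed: `"cdr3aa"` (CDR3 beta
#'   amino acids alone, the clone definition used for matching across
#'   samples), `"cdr3aa_v"` (CDR3 beta + V gene, default for bulk data) or
#'   `"paired"` (CDR3 beta + CDR3 alpha when available).
#' @return Object of class `tcr_repertoire`.
#' @export
new_repertoire <- function(clonotypes, sample_id = "sample",
                           cohort_label = NA_character_,
                           sort_label = NA_character_,
                           key_scheme = c("cdr3aa", "cdr3aa_v", "paired")) {
  key_scheme <- match.arg(key_scheme)
  if (!is.data.frame(clonotypes))
    stop_tcrdrive("parameter_error", "clonotypes must be a data.frame")
  if (nrow(clonotypes) == 0L)
    stop_tcrdrive("empty_repertoire", "repertoire '%s' has no clonotypes", sample_id)
  need <- c("cdr3_aa", "read_count")
  missing <- setdiff(need, names(clonotypes))
  if (length(missing))
    stop_tcrdrive("format_error", "missing required column(s): %s",
                  paste(missing, collapse = ", "))

  df <- data.frame(
    cdr3_aa = as.character(clonotypes$cdr3_aa),
    cdr3_aa_alpha = as.character(clonotypes$cdr3_aa_alpha %||%
                                   rep(NA_character_, nrow(clonotypes))),
    v_call = as.character(clonotypes$v_call %||% rep(NA_character_, nrow(clonotypes))),
    j_call = as.character(clonotypes$j_call %||% rep(NA_character_, nrow(clonotypes))),
    read_count = as.integer(clonotypes$read_count),
    productive = as.logical(clonotypes$productive %||% rep(TRUE, nrow(clonotypes))),
    leukemic = as.logical(clonotypes$leukemic %||% rep(NA, nrow(clonotypes))),
    stringsAsFactors = FALSE
  )

  if (anyNA(df$read_count) || any(df$read_count < 1L))
    stop_tcrdrive("validation_error", "read_count must be a positive integer for every clonotype")

  bad <- which(df$productive & !grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")),
                                      df$cdr3_aa))
  if (length(bad))
    stop_tcrdrive("validation_error",
                  "non-amino-acid characters in productive CDR3 at row(s): %s",
                  paste(utils::head(bad, 10L), collapse = ", "))

  if ("key" %in% names(clonotypes)) {
    df$key <- as.character(clonotypes$key)
  } else {
    df$key <- make_clonotype_key(df, key_scheme)
  }

  # Aggregate rows that collapse to the same key.
  if (anyDuplicated(df$key)) {
    counts <- tapply(df$read_count, df$key, sum)
    first <- df[!duplicated(df$key), , drop = FALSE]
    first$read_count <- as.integer(counts[first$key])
    df <- first
  }

  df <- df[order_stable(-df$read_count, df$cdr3_aa, df$key), , drop = FALSE]
  rownames(df) <- NULL
  total <- sum(df$read_count)
  df$frequency <- df$read_count / total

  structure(list(
    sample_id = sample_id,
    cohort_label = cohort_label,
    sort_label = sort_label,
    key_scheme = key_scheme,
    clonotypes = df,
    total_reads = as.integer(total)
  ), class = "tcr_repertoire")
}

make_clonotype_key <- function(df, key_scheme) {
  switch(key_scheme,
    cdr3aa = df$cdr3_aa,
    cdr3aa_v = ifelse(is.na(df$v_call), df$cdr3_aa,
                      paste(df$cdr3_aa, df$v_call, sep = "|")),
    paired = ifelse(is.na(df$cdr3_aa_alpha), df$cdr3_aa,
                    paste(df$cdr3_aa, df$cdr3_aa_alpha, sep = "|"))
  )
}

#' Validate a repertoire object
#'
#' Checks the structural invariants: positive counts, total reads equal to
#' the count sum, frequencies summing to one (1e-9), unique keys, and
#' amino-acid alphabet for productive CDR3s.
#'
#' @param rep A `tcr_repertoire`.
#' @return The repertoire, invisibly, if valid; otherwise an error.
#' @export
validate_repertoire <- function(rep) {
  if (!inherits(rep, "tcr_repertoire"))
    stop_tcrdrive("parameter_error", "not a tcr_repertoire")
  df <- rep$clonotypes
  if (nrow(df) == 0L)
    stop_tcrdrive("empty_repertoire", "repertoire '%s' is empty", rep$sample_id)
  if (any(df$read_count < 1L))
    stop_tcrdrive("validation_error", "read_count < 1")
  if (rep$total_reads != sum(df$read_count))
    stop_tcrdrive("validation_error", "total_reads != sum(read_count)")
  if (abs(sum(df$frequency) - 1) > 1e-9)
    stop_tcrdrive("validation_error", "frequencies do not sum to 1")
  if (anyDuplicated(df$key))
    stop_tcrdrive("validation_error", "duplicate clonotype keys")
  invisible(rep)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire '%s' (%s, %s): %d clonotypes, %d reads\n",
              x$sample_id,
              ifelse(is.na(x$cohort_label), "-", x$cohort_label),
              ifelse(is.na(x$sort_label), "-", x$sort_label),
              nrow(x$clonotypes), x$total_reads))
  cat(sprintf("  top clone: %s (%.1f%%)\n",
              x$clonotypes$cdr3_aa[which.max(x$clonotypes$frequency)],
              100 * max(x$clonotypes$frequency)))
  invisible(x)
}

# Rebuild frequencies/ordering after any subsetting of the clonotype table.
rebuild_repertoire <- function(rep, df) {
  if (nrow(df) == 0L)
    stop_tcrdrive("empty_repertoire",
                  "operation removed every clonotype of '%s'", rep$sample_id)
  df <- df[order_stable(-df$read_count, df$cdr3_aa, df$key), , drop = FALSE]
  rownames(df) <- NULL
  rep$total_reads <- as.integer(sum(df$read_count))
  df$frequency <- df$read_count / rep$total_reads
  rep$clonotypes <- df
  rep
}

#' Remove non-functional clonotypes
#'
#' Drops clonotypes whose rearrangement is non-productive (out-of-frame or
#' containing a stop codon) and renormalises frequencies over the
#' remainder. When the input carried no productivity flag, the flag was
#' already derived at read time from the CDR3 sequence (see
#' [read_repertoire()]).
#'
#' @param rep A `tcr_repertoire`.
#' @return The filtered repertoire.
#' @export
filter_productive <- function(rep) {
  validate_repertoire(rep)
  keep <- rep$clonotypes$productive
  if (!any(keep))
    stop_tcrdrive("empty_repertoire",
                  "all clonotypes of '%s' are non-productive", rep$sample_id)
  rebuild_repertoire(rep, rep$clonotypes[keep, , drop = FALSE])
}

#' Subsample a repertoire to a fixed read depth
#'
#' Draws exactly `depth` reads without replacement from the repertoire's
#' read multiset (multivariate hypergeometric), drops clonotypes with zero
#' drawn reads and recomputes frequencies. Samples with fewer than `depth`
#' total reads are not subsampled: they are excluded from analysis and an
#' exclusion marker is returned instead, mirroring the fixed-depth
#' rarefaction rule under which all repertoires are compared at the same
#' depth (30,000 reads by default) and shallower samples are removed.
#'
#' @param rep A `tcr_repertoire`.
#' @param depth Target read depth (positive integer).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A subsampled `tcr_repertoire`, or an object of class
#'   `tcrdrive_exclusion` when `total_reads < depth`.
#' @seealso [is_excluded()]
#' @export
subsample_repertoire <- function(rep, depth, seed = NULL) {
  validate_repertoire(rep)
  if (!is_count(depth))
    stop_tcrdrive("parameter_error", "depth must be a positive integer")
  depth <- as.integer(depth)
  if (rep$total_reads < depth) {
    return(structure(list(sample_id = rep$sample_id,
                          total_reads = rep$total_reads,
                          depth = depth,
                          reason = "below_depth"),
                     class = "tcrdrive_exclusion"))
  }
  if (rep$total_reads == depth) return(rep)

  counts <- rep$clonotypes$read_count
  drawn <- with_seed(seed, rmvhyper(counts, depth))
  df <- rep$clonotypes
  df$read_count <- drawn
  df <- df[drawn > 0L, , drop = FALSE]
  rebuild_repertoire(rep, df)
}

# Sequential hypergeometric draw of `k` items without replacement from urns
# with the given counts (multivariate hypergeometric).
rmvhyper <- function(counts, k) {
  n <- length(counts)
  remaining <- sum(counts)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (k == 0L) break
    ci <- counts[i]
    remaining <- remaining - ci
    if (remaining == 0L) {
      out[i] <- k
      k <- 0L
    } else {
      d <- stats::rhyper(1L, ci, remaining, k)
      out[i] <- d
      k <- k - d
    }
  }
  out
}

#' Test for a subsampling exclusion marker
#' @param x Object returned by [subsample_repertoire()].
#' @return TRUE if `x` marks an excluded (too shallow) sample.
#' @export
is_excluded <- function(x) inherits(x, "tcrdrive_exclusion")

#' @export
print.tcrdrive_exclusion <- function(x, ...) {
  cat(sprintf("sample '%s' excluded: %d reads < depth %d\n",
              x$sample_id, x$total_reads, x$depth))
  invisible(x)
}

#' Remove named clonotypes from a repertoire
#'
#' Used by the leukemic-exclusion analysis variant: the leukemic clones (or
#' the largest clone of a comparison sample) are removed and frequencies
#' renormalised over the non-leukemic remainder before rarefaction.
#'
#' @param rep A `tcr_repertoire`.
#' @param keys Character vector of clonotype keys to remove (may be empty).
#' @return The repertoire without the named clonotypes.
#' @export
exclude_clonotypes <- function(rep, keys) {
  validate_repertoire(rep)
  if (length(keys) == 0L) return(rep)
  unknown <- setdiff(keys, rep$clonotypes$key)
  if (length(unknown))
    stop_tcrdrive("key_error", "unknown clonotype key(s): %s",
                  paste(utils::head(unknown, 5L), collapse = ", "))
  rebuild_repertoire(rep,
    rep$clonotypes[!(rep$clonotypes$key %in% keys), , drop = FALSE])
}
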