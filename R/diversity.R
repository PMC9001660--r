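#' Gini clonality index
#'
#' Inequality of the clone-size distribution, computed as the mean absolute
#' difference between all pairs of clone frequencies scaled by twice the
#' mean: `G = sum_ij |x_i - x_j| / (2 n^2 mu)`. G is 0 for a perfectly even
#' repertoire and approaches 1 as a single clone dominates; higher means
#' more clonal. A single-clone repertoire scores 0 by this formula. The
#' index is invariant to scaling, so counts or frequencies give the same
#' value.
#'
#' @param x Positive clone sizes (counts or frequencies).
#' @return Gini index in `[0, 1 - 1/n]`.
#' @export
gini_index <- function(x) {
  if (length(x) == 0L)
    stop_tcrdrive("parameter_error", "empty clone-size vector")
  if (any(!is.finite(x)) || any(x <= 0))
    stop_tcrdrive("parameter_error", "clone sizes must be positive and finite")
  n <- length(x)
  if (n == 1L) return(0)
  # sum_ij |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)  for sorted x
  xs <- sort(x)
  s <- 2 * sum((2 * seq_len(n) - n - 1) * xs)
  s / (2 * n^2 * mean(x))
}

#' Shannon diversity of a repertoire
#'
#' Shannon entropy of the clone frequency distribution in bits,
#' `H = -sum p_i log2 p_i`, and its normalised form `H / log2(n)` (Pielou
#' evenness), defined as 0 for a single-clone repertoire.
#'
#' @param p Clone frequencies summing to 1 (tolerance 1e-9).
#' @return List with `shannon_bits` and `shannon_normalized`.
#' @export
shannon_metrics <- function(p) {
  if (length(p) == 0L)
    stop_tcrdrive("parameter_error", "empty frequency vector")
  if (any(!is.finite(p)) || any(p <= 0))
    stop_tcrdrive("parameter_error", "frequencies must be positive and finite")
  if (abs(sum(p) - 1) > 1e-9)
    stop_tcrdrive("parameter_error", "frequencies must sum to 1")
  h <- -sum(p * log2(p))
  n <- length(p)
  list(shannon_bits = h,
       shannon_normalized = if (n > 1L) h / log2(n) else 0)
}

#' Expansion class of a clonotype
#'
#' Classifies a clonotype by the number of times its TCR was detected:
#' singleton (detected once), expanded (detected >= 2 times) and
#' hyperexpanded (detected >= 10 times). By default the classes are
#' reported as exclusive bins (an expanded clone detected >= 10 times is
#' hyperexpanded only); with `cumulative = TRUE` the expanded class
#' includes hyperexpanded clones, useful for threshold sensitivity
#' analyses.
#'
#' @param read_count Integer vector of detection counts (>= 1).
#' @param config A [pipeline_config()] (thresholds `expanded_min`,
#'   `hyperexpanded_min`).
#' @param cumulative Report `expanded` as ">= expanded_min" including
#'   hyperexpanded clones.
#' @return Character vector of class labels.
#' @export
classify_expansion <- function(read_count, config = NULL, cumulative = FALSE) {
  config <- as_config(config)
  if (any(read_count < 1L))
    stop_tcrdrive("parameter_error", "read_count must be >= 1")
  out <- ifelse(read_count >= config$hyperexpanded_min, "hyperexpanded",
                ifelse(read_count >= config$expanded_min, "expanded",
                       "singleton"))
  if (cumulative) out[out == "hyperexpanded"] <- "expanded"
  out
}

#' Per-sample expansion profile
#'
#' Counts of clonotypes and fractions of cells/reads per expansion class.
#' Class cell fractions sum to 1; the classes are exclusive bins.
#'
#' @param rep A `tcr_repertoire`.
#' @param config A [pipeline_config()].
#' @return data.frame with one row per class: `class`, `n_clonotypes`,
#'   `cell_fraction`.
#' @export
expansion_profile <- function(rep, config = NULL) {
  validate_repertoire(rep)
  config <- as_config(config)
  cls <- classify_expansion(rep$clonotypes$read_count, config)
  levels <- c("singleton", "expanded", "hyperexpanded")
  n <- vapply(levels, function(l) sum(cls == l), integer(1))
  frac <- vapply(levels, function(l)
    sum(rep$clonotypes$read_count[cls == l]) / rep$total_reads, numeric(1))
  data.frame(sample_id = rep$sample_id, class = levels,
             n_clonotypes = n, cell_fraction = frac,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of cells in hyperexpanded clonotypes
#'
#' Proportion of the repertoire's reads/cells that belong to clonotypes
#' detected at least `hyperexpanded_min` (default 10) times.
#'
#' @inheritParams expansion_profile
#' @return A fraction in `[0, 1]`.
#' @export
hyperexpanded_cell_fraction <- function(rep, config = NULL) {
  validate_repertoire(rep)
  config <- as_config(config)
  cnt <- rep$clonotypes$read_count
  sum(cnt[cnt >= config$hyperexpanded_min]) / rep$total_reads
}

#' Diversity record for one repertoire
#'
#' One row combining the clonality metrics used for cohort comparison:
#' Gini index, Shannon entropy (bits and normalised), clonotype count and
#' top-clone frequency.
#'
#' @param rep A `tcr_repertoire`.
#' @return One-row data.frame (`sample_id`, `gini`, `shannon_bits`,
#'   `shannon_normalized`, `n_clonotypes`, `top_clone_frequency`).
#' @export
diversity_record <- function(rep) {
  validate_repertoire(rep)
  p <- rep$clonotypes$frequency
  sh <- shannon_metrics(p)
  data.frame(sample_id = rep$sample_id,
             gini = gini_index(p),
             shannon_bits = sh$shannon_bits,
             shannon_normalized = sh$shannon_normalized,
             n_clonotypes = length(p),
             top_clone_frequency = max(p),
             stringsAsFactors = FALSE)
}

#' Search query clonotypes across a cohort of repertoires
#'
#' For every query, counts in how many cohort repertoires an exact match
#' exists under the chosen scheme (CDR3 beta amino acids alone — the clone
#' definition used across samples — or CDR3 + V gene), and records each
#' match's within-repertoire frequency. This is the occurrence analysis
#' used to ask whether leukemic clonotypes are ever seen in healthy
#' control repertoires.
#'
#' @param queries Character vector of query keys (CDR3 amino-acid
#'   sequences, or "CDR3|V" strings under `cdr3aa_v`).
#' @param cohort List of `tcr_repertoire` objects.
#' @param match_scheme `"cdr3aa"` (default) or `"cdr3aa_v"`.
#' @return List with `records` (data.frame: `query`,
#'   `n_repertoires_found`, `n_repertoires_searched`, `max_frequency`,
#'   `mean_frequency`) and `matches` (data.frame of every individual
#'   match: `query`, `sample_id`, `frequency`).
#' @export
occurrence_search <- function(queries, cohort,
                              match_scheme = c("cdr3aa", "cdr3aa_v")) {
  match_scheme <- match.arg(match_scheme)
  if (length(cohort) == 0L)
    stop_tcrdrive("parameter_error", "cohort must contain at least one repertoire")
  if (length(queries) == 0L) {
    warning("empty query set; returning no occurrence records")
    return(list(records = data.frame(), matches = data.frame()))
  }
  lapply(cohort, validate_repertoire)

  match_key <- function(rep) {
    df <- rep$clonotypes
    if (match_scheme == "cdr3aa") df$cdr3_aa
    else ifelse(is.na(df$v_call), df$cdr3_aa, paste(df$cdr3_aa, df$v_call, sep = "|"))
  }

  matches <- do.call(rbind, lapply(cohort, function(rep) {
    keys <- match_key(rep)
    hit <- which(keys %in% queries)
    if (length(hit) == 0L) return(NULL)
    # a query may match several clonotypes (same CDR3, different V): sum
    freq <- tapply(rep$clonotypes$frequency[hit], keys[hit], sum)
    data.frame(query = names(freq), sample_id = rep$sample_id,
               frequency = as.numeric(freq),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(matches))
    matches <- data.frame(query = character(), sample_id = character(),
                          frequency = numeric(), stringsAsFactors = FALSE)

  records <- data.frame(
    query = queries,
    n_repertoires_found = vapply(queries, function(q)
      sum(matches$query == q), integer(1)),
    n_repertoires_searched = length(cohort),
    max_frequency = vapply(queries, function(q) {
      f <- matches$frequency[matches$query == q]
      if (length(f)) max(f) else NA_real_
    }, numeric(1)),
    mean_frequency = vapply(queries, function(q) {
      f <- matches$frequency[matches$query == q]
      if (length(f)) mean(f) else NA_real_
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(records = records, matches = matches)
}
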