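#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' The defaults encode the published analysis conditions: repertoires are
#' rarefied to 30,000 reads (samples below that depth are excluded), a clone
#' is called leukemic when it explains strictly more than 5% of the
#' repertoire, expansion classes use the >=2 / >=10 cell cut-offs, and a
#' drive-supporting specificity group must hold at least two distinct TCRs.
#' Motif-grouping defaults (k in {3,4}, CDR3 trimmed by 3 leading / 2
#' trailing residues, one-sided Fisher p < 1e-3 with fold-enrichment >= 10,
#' Hamming distance <= 1 for global links) follow the conventions of
#' GLIPH-style clustering tools.
#'
#' @param subsample_depth Fixed read depth for rarefaction (reads; templates
#'   for immunoSEQ input, cells for single-cell input).
#' @param leukemic_threshold Repertoire fraction above which (strictly) a
#'   clone is called leukemic.
#' @param expanded_min,hyperexpanded_min Read-count cut-offs for the
#'   expanded (>=2) and hyperexpanded (>=10) classes.
#' @param motif_lengths Integer vector of k-mer lengths for local motifs.
#' @param cdr3_trim Length-2 integer vector: residues trimmed from the
#'   leading and trailing ends of the CDR3 before motif extraction.
#' @param enrichment_alpha Significance level for motif enrichment.
#' @param min_fold Minimum fold-enrichment over the reference.
#' @param min_group_size Minimum distinct TCRs in a drive-supporting group.
#' @param hamming_max Maximum substitutions between trimmed cores for a
#'   global (whole-CDR3) link.
#' @param score_bins Expression bins for module-score control matching.
#' @param n_control_genes Control genes drawn per gene-set gene.
#' @param pseudocount Offset used by the geometric-mean score.
#' @param rng_seed Default seed for stochastic steps.
#' @return An object of class `tcrdrive_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$subsample_depth
#' @export
pipeline_config <- function(subsample_depth = 30000L,
                            leukemic_threshold = 0.05,
                            expanded_min = 2L,
                            hyperexpanded_min = 10L,
                            motif_lengths = c(3L, 4L),
                            cdr3_trim = c(3L, 2L),
                            enrichment_alpha = 1e-3,
                            min_fold = 10,
                            min_group_size = 2L,
                            hamming_max = 1L,
                            score_bins = 24L,
                            n_control_genes = 100L,
                            pseudocount = 1,
                            rng_seed = 1L) {
  if (!is_count(subsample_depth))
    stop_tcrdrive("parameter_error", "subsample_depth must be a positive integer")
  if (!is.numeric(leukemic_threshold) || leukemic_threshold <= 0 ||
      leukemic_threshold >= 1)
    stop_tcrdrive("parameter_error", "leukemic_threshold must lie in (0,1)")
  if (!is_count(expanded_min) || !is_count(hyperexpanded_min) ||
      hyperexpanded_min <= expanded_min)
    stop_tcrdrive("parameter_error", "expansion thresholds must be increasing positive integers")
  if (!all(vapply(motif_lengths, is_count, logical(1))))
    stop_tcrdrive("parameter_error", "motif_lengths must be positive integers")
  if (length(cdr3_trim) != 2L || any(cdr3_trim < 0))
    stop_tcrdrive("parameter_error", "cdr3_trim must be two non-negative integers")
  if (!is.numeric(enrichment_alpha) || enrichment_alpha <= 0 || enrichment_alpha >= 1)
    stop_tcrdrive("parameter_error", "enrichment_alpha must lie in (0,1)")
  if (!is.numeric(min_fold) || min_fold <= 0)
    stop_tcrdrive("parameter_error", "min_fold must be positive")
  if (!is_count(min_group_size))
    stop_tcrdrive("parameter_error", "min_group_size must be a positive integer")
  if (!is_count(hamming_max, positive = FALSE))
    stop_tcrdrive("parameter_error", "hamming_max must be a non-negative integer")
  if (!is_count(score_bins) || !is_count(n_control_genes))
    stop_tcrdrive("parameter_error", "score_bins and n_control_genes must be positive integers")
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop_tcrdrive("parameter_error", "pseudocount must be non-negative")

  structure(list(
    subsample_depth = as.integer(subsample_depth),
    leukemic_threshold = leukemic_threshold,
    expanded_min = as.integer(expanded_min),
    hyperexpanded_min = as.integer(hyperexpanded_min),
    motif_lengths = sort(unique(as.integer(motif_lengths))),
    cdr3_trim = as.integer(cdr3_trim),
    enrichment_alpha = enrichment_alpha,
    min_fold = min_fold,
    min_group_size = as.integer(min_group_size),
    hamming_max = as.integer(hamming_max),
    score_bins = as.integer(score_bins),
    n_control_genes = as.integer(n_control_genes),
    pseudocount = pseudocount,
    rng_seed = as.integer(rng_seed)
  ), class = "tcrdrive_config")
}

#' @export
print.tcrdrive_config <- function(x, ...) {
  cat("tcrdrive pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "tcrdrive_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop_tcrdrive("parameter_error", "config must be NULL, a list, or a tcrdrive_config")
}
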