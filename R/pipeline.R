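# End-to-end orchestration: read -> filter -> identify leukemic ->
# subsample -> group -> drive call -> cohort statistics -> report tables.

load_sample <- function(entry) {
  rep <- read_repertoire(entry$path, format = entry$format,
                         key_scheme = entry$key_scheme %||% "cdr3aa",
                         sample_id = entry$sample_id,
                         cohort_label = entry$cohort_label %||% NA_character_,
                         sort_label = entry$sort_label %||% NA_character_)
  filter_productive(rep)
}

#' Run the cohort antigen-drive analysis
#'
#' Per sample: remove non-functional clonotypes, identify leukemic clones
#' (>5% rule or annotation), rarefy to the configured depth (shallow
#' samples are excluded, not errors), build specificity groups against the
#' reference and call antigen drive ([classify_drive()]). Cohort level:
#' per-cohort driven proportions with one-sided Fisher comparisons against
#' the focal cohort ([compare_drive_prevalence()]), a diversity table, a
#' box-plot-ready summary of clone sizes by drive status, and a
#' reproducibility manifest (config echo, per-sample status, seeds).
#' Indeterminate calls (leukemic clone lost to rarefaction) are excluded
#' from cohort denominators and reported separately.
#'
#' @param samples Either a list of `tcr_repertoire` objects, or the path
#'   to / data.frame of a sample manifest with columns `sample_id`,
#'   `path`, `format`, `cohort_label`, optional `sort_label`,
#'   `key_scheme`, `leukemic_keys` (";"-separated annotation).
#' @param reference Reference repertoire / CDR3 vector / index.
#' @param config A [pipeline_config()].
#' @param mode `"standard"` or `"exclude_leukemic"` (see
#'   [classify_drive()]).
#' @param seed Master seed; per-sample subsampling seeds are derived from
#'   it.
#' @param annotations Optional named list (by sample_id) of leukemic key
#'   annotations overriding the frequency rule.
#' @param out_dir Optional output directory; when given, writes
#'   `drive_calls.tsv`, `cohort_summary.tsv`, `diversity.tsv`,
#'   `clone_size_summary.tsv` and `manifest.json` there.
#' @param strict Abort on the first sample-level error instead of
#'   recording it in the manifest.
#' @return Object of class `tcrdrive_drive_analysis`: list with `calls`,
#'   `cohort_summary`, `diversity`, `clone_size_by_drive` (test summary or
#'   NULL), `manifest`, and `per_sample` (the individual
#'   `tcrdrive_drive_calls` objects).
#' @export
run_drive_analysis <- function(samples, reference, config = NULL,
                               mode = c("standard", "exclude_leukemic"),
                               seed = NULL, annotations = NULL,
                               out_dir = NULL, strict = FALSE) {
  config <- as_config(config)
  mode <- match.arg(mode)
  seed <- seed %||% config$rng_seed

  if (is.character(samples) && length(samples) == 1L) samples <- read_tsv(samples)
  if (is.data.frame(samples)) {
    manifest_df <- samples
    entries <- lapply(seq_len(nrow(samples)), function(i) as.list(samples[i, ]))
    reps <- NULL
  } else {
    entries <- NULL
    reps <- samples
  }
  n <- length(entries %||% reps)
  if (n == 0L) stop_tcrdrive("parameter_error", "no samples given")

  ref <- as_reference_index(reference, config)
  seeds <- derive_seeds(seed, n)

  status <- character(n)
  sample_ids <- character(n)
  per_sample <- vector("list", n)
  all_calls <- list()

  for (i in seq_len(n)) {
    res <- tryCatch({
      rep <- if (is.null(reps)) load_sample(entries[[i]]) else {
        validate_repertoire(reps[[i]])
        filter_productive(reps[[i]])
      }
      ann <- annotations[[rep$sample_id]] %||% {
        if (!is.null(entries) && !is.null(entries[[i]]$leukemic_keys) &&
            !is.na(entries[[i]]$leukemic_keys) &&
            nzchar(entries[[i]]$leukemic_keys))
          strsplit(entries[[i]]$leukemic_keys, ";", fixed = TRUE)[[1]]
        else NULL
      }
      leuk <- identify_leukemic_clones(rep, config, annotation = ann)
      dc <- classify_drive(rep, ref, leuk, config, mode = mode,
                           seed = seeds[i])
      list(rep = rep, dc = dc)
    }, tcrdrive_error = function(e) {
      if (strict) stop(e)
      e
    })

    if (inherits(res, "condition")) {
      sample_ids[i] <- if (!is.null(entries)) {
        as.character(entries[[i]]$sample_id %||% sprintf("sample_%d", i))
      } else reps[[i]]$sample_id %||% sprintf("sample_%d", i)
      status[i] <- paste0("error: ", conditionMessage(res))
      next
    }
    sample_ids[i] <- res$rep$sample_id
    if (is_excluded(res$dc)) {
      status[i] <- "excluded_depth"
      per_sample[[i]] <- res$dc
      next
    }
    calls <- res$dc$calls
    if (nrow(calls) > 0L) {
      calls$cohort_label <- res$rep$cohort_label
      calls$leukemic_frequency <- res$rep$clonotypes$frequency[
        match(calls$leukemic_key, res$rep$clonotypes$key)]
      all_calls[[length(all_calls) + 1L]] <- calls
    }
    status[i] <- if (nrow(calls) > 0L && anyNA(calls$driven))
      "indeterminate" else "included"
    per_sample[[i]] <- res$dc
  }

  calls <- if (length(all_calls)) do.call(rbind, all_calls) else
    data.frame(sample_id = character(), leukemic_key = character(),
               driven = logical(), cohort_label = character(),
               leukemic_frequency = numeric(), stringsAsFactors = FALSE)

  # cohort summary: a sample counts as driven when any of its leukemic
  # clones is driven; indeterminate-only samples drop out of denominators
  cohort_summary <- NULL
  if (nrow(calls) > 0L) {
    ok <- calls[!is.na(calls$driven), , drop = FALSE]
    if (nrow(ok) > 0L) {
      per_samp <- tapply(ok$driven, ok$sample_id, any)
      coh <- ok$cohort_label[match(names(per_samp), ok$sample_id)]
      coh[is.na(coh)] <- "unlabelled"
      cohort_summary <- data.frame(
        cohort = sort(unique(coh)),
        n_samples = as.integer(table(coh)[sort(unique(coh))]),
        n_driven = as.integer(tapply(per_samp, coh, sum)[sort(unique(coh))]),
        stringsAsFactors = FALSE)
      if (nrow(cohort_summary) >= 2L)
        cohort_summary <- compare_drive_prevalence(cohort_summary)
    }
  }

  diversity <- do.call(rbind, lapply(per_sample[status == "included" |
                                                  status == "indeterminate"],
                                     function(dc) {
    if (is.null(dc) || is_excluded(dc)) return(NULL)
    diversity_record(dc$repertoire)
  }))

  clone_size_by_drive <- NULL
  size_summary <- NULL
  ok <- calls[!is.na(calls$driven), , drop = FALSE]
  if (nrow(ok) > 0L && length(unique(ok$driven)) == 2L) {
    clone_size_by_drive <- compare_clone_sizes_by_drive(
      ok$leukemic_frequency, ok$driven)
    size_summary <- do.call(rbind, lapply(c(TRUE, FALSE), function(d) {
      bs <- boxplot_stats(ok$leukemic_frequency[ok$driven == d])
      data.frame(driven = d, median = bs$median, q1 = bs$q1, q3 = bs$q3,
                 whisker_low = bs$whisker_low, whisker_high = bs$whisker_high,
                 n = bs$n, stringsAsFactors = FALSE)
    }))
  }

  manifest <- list(
    config = unclass(config),
    mode = mode,
    master_seed = as.integer(seed),
    samples = data.frame(sample_id = sample_ids, status = status,
                         subsample_seed = seeds, stringsAsFactors = FALSE),
    gene_set_versions = vapply(packaged_gene_sets(), length, integer(1))
  )

  out <- structure(list(calls = calls, cohort_summary = cohort_summary,
                        diversity = diversity,
                        clone_size_by_drive = clone_size_by_drive,
                        clone_size_summary = size_summary,
                        manifest = manifest, per_sample = per_sample),
                   class = "tcrdrive_drive_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(format_numeric_df(calls), file.path(out_dir, "drive_calls.tsv"))
    if (!is.null(cohort_summary))
      write_tsv(format_numeric_df(cohort_summary),
                file.path(out_dir, "cohort_summary.tsv"))
    if (!is.null(diversity))
      write_tsv(format_numeric_df(diversity), file.path(out_dir, "diversity.tsv"))
    if (!is.null(size_summary))
      write_tsv(format_numeric_df(size_summary),
                file.path(out_dir, "clone_size_summary.tsv"))
    manifest_json <- manifest
    manifest_json$outputs <- list.files(out_dir)
    jsonlite::write_json(manifest_json, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# format numeric columns with full precision for byte-stable TSVs
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format(df[[j]], digits = 15)
  }
  df
}

#' @export
print.tcrdrive_drive_analysis <- function(x, ...) {
  st <- table(x$manifest$samples$status)
  cat("tcrdrive drive analysis\n")
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  cat(sprintf("  leukemic clones called: %d (%d driven, %d indeterminate)\n",
              nrow(x$calls), sum(x$calls$driven, na.rm = TRUE),
              sum(is.na(x$calls$driven))))
  if (!is.null(x$cohort_summary)) {
    cat("  cohort summary:\n")
    print(x$cohort_summary, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.tcrdrive_drive_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$clone_size_by_drive)) {
    z <- object$clone_size_by_drive
    cat(sprintf("  clone size driven vs non-driven: U = %.1f, p = %.3g (medians %.3f vs %.3f)\n",
                z$statistic, z$p_value, z$median_driven, z$median_not_driven))
  }
  invisible(object)
}

#' Batch diversity and expansion tables
#'
#' @param samples List of `tcr_repertoire` objects (or a manifest as in
#'   [run_drive_analysis()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for `diversity.tsv` and
#'   `expansion.tsv`.
#' @return List with `diversity` (one row per sample, see
#'   [diversity_record()]) and `expansion` (stacked
#'   [expansion_profile()] rows).
#' @export
run_diversity <- function(samples, config = NULL, out_dir = NULL) {
  config <- as_config(config)
  if (is.character(samples) && length(samples) == 1L) samples <- read_tsv(samples)
  if (is.data.frame(samples))
    samples <- lapply(seq_len(nrow(samples)), function(i)
      load_sample(as.list(samples[i, ])))
  diversity <- do.call(rbind, lapply(samples, diversity_record))
  expansion <- do.call(rbind, lapply(samples, expansion_profile,
                                     config = config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(format_numeric_df(diversity), file.path(out_dir, "diversity.tsv"))
    write_tsv(format_numeric_df(expansion), file.path(out_dir, "expansion.tsv"))
  }
  list(diversity = diversity, expansion = expansion)
}

#' Batch gene-set scores and differential expression
#'
#' @param mat Genes x cells matrix (see [read_expression_matrix()]).
#' @param gene_sets Named list of gene vectors; defaults to
#'   [packaged_gene_sets()].
#' @param group_labels Optional two-group label vector for [de_test()].
#' @param config A [pipeline_config()].
#' @param seed Seed for the module-score control draw.
#' @param out_dir Optional directory for `scores.tsv` / `de.tsv`.
#' @return List with `scores` (long data.frame: `cell`, `set`, `score`)
#'   and `de` (data.frame or NULL).
#' @export
run_scores <- function(mat, gene_sets = NULL, group_labels = NULL,
                       config = NULL, seed = NULL, out_dir = NULL) {
  config <- as_config(config)
  gene_sets <- gene_sets %||% packaged_gene_sets()
  seed <- seed %||% config$rng_seed
  scores <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    present <- intersect(gene_sets[[nm]], rownames(mat))
    if (length(present) == 0L) return(NULL)
    s <- module_score(mat, present, config, seed = seed)
    data.frame(cell = names(s), set = nm, score = as.numeric(s),
               n_genes_used = length(present), stringsAsFactors = FALSE)
  }))
  de <- NULL
  if (!is.null(group_labels)) de <- de_test(mat, group_labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(scores))
      write_tsv(format_numeric_df(scores), file.path(out_dir, "scores.tsv"))
    if (!is.null(de))
      write_tsv(format_numeric_df(de), file.path(out_dir, "de.tsv"))
  }
  list(scores = scores, de = de)
}
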