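#' Identify leukemic clones in a repertoire
#'
#' By default a clonotype is called leukemic when it explains strictly more
#' than `leukemic_threshold` (default 5%) of the repertoire, evaluated on
#' the repertoire as given (before any subsampling). Alternatively an
#' external annotation (a list of clonotype keys curated from flow
#' cytometry, amplicon sequencing or a prior publication) can be supplied
#' and is returned verbatim after validation against the repertoire.
#'
#' @param rep A `tcr_repertoire`.
#' @param config A [pipeline_config()].
#' @param annotation Optional character vector of annotated leukemic keys.
#' @return Character vector of leukemic clonotype keys, largest clone
#'   first (possibly empty).
#' @export
identify_leukemic_clones <- function(rep, config = NULL, annotation = NULL) {
  validate_repertoire(rep)
  config <- as_config(config)
  if (!is.null(annotation)) {
    unknown <- setdiff(annotation, rep$clonotypes$key)
    if (length(unknown))
      stop_tcrdrive("key_error", "annotated key(s) absent from repertoire: %s",
                    paste(utils::head(unknown, 5L), collapse = ", "))
    return(as.character(annotation))
  }
  df <- rep$clonotypes
  hit <- df$frequency > config$leukemic_threshold  # strict >
  df$key[hit][order(-df$frequency[hit])]
}

#' Classify leukemic clones as antigen-driven or not
#'
#' The antigen-drive call asks whether a leukemic clone shares amino
#' acid-level TCR similarities with the non-leukemic repertoire of the
#' same sample. The repertoire is rarefied to `subsample_depth` reads,
#' specificity groups are built against the reference (see
#' [build_specificity_groups()]), and a leukemic clone is called *driven*
#' when its group is significant, holds at least `min_group_size` distinct
#' TCRs, and contains at least one non-leukemic partner clonotype.
#'
#' Two modes:
#' \describe{
#'   \item{`standard`}{the whole repertoire (leukemic clone included) is
#'     subsampled to depth. A leukemic clone that loses all its reads in
#'     the draw cannot be classified: its call is `NA` (indeterminate) and
#'     it is excluded from cohort denominators.}
#'   \item{`exclude_leukemic`}{the leukemic clones are removed first and
#'     only the non-leukemic repertoire is subsampled; the leukemic CDR3s
#'     are then re-inserted as query nodes and classified identically.
#'     This controls for the dominant clone eating most of the fixed
#'     depth.}
#' }
#'
#' @param rep A `tcr_repertoire` (pre-subsampling; leukemic calls are made
#'   on these frequencies).
#' @param reference Reference repertoire / CDR3 vector / index for
#'   enrichment.
#' @param leukemic_keys Character vector of leukemic clonotype keys (may
#'   be empty).
#' @param config A [pipeline_config()].
#' @param mode `"standard"` or `"exclude_leukemic"`.
#' @param seed Integer seed controlling the subsampling draw.
#' @return Object of class `tcrdrive_drive_calls`: list with `calls` (one
#'   row per leukemic clone: `sample_id`, `leukemic_key`, `driven`,
#'   `supporting_group_id`, `n_group_members`, `n_nonleukemic_partners`,
#'   `any_significant_group`, `mode`, `subsample_seed`), `groups` (the
#'   `tcrdrive_groups` object) and `repertoire` (the analysed, subsampled
#'   repertoire). Returns the exclusion marker unchanged when the sample
#'   is below depth.
#' @export
classify_drive <- function(rep, reference, leukemic_keys, config = NULL,
                           mode = c("standard", "exclude_leukemic"),
                           seed = NULL) {
  config <- as_config(config)
  mode <- match.arg(mode)
  validate_repertoire(rep)
  seed <- seed %||% config$rng_seed
  unknown <- setdiff(leukemic_keys, rep$clonotypes$key)
  if (length(unknown))
    stop_tcrdrive("key_error", "leukemic key(s) absent from repertoire: %s",
                  paste(utils::head(unknown, 5L), collapse = ", "))

  # mark leukemic clonotypes on the repertoire
  rep$clonotypes$leukemic <- rep$clonotypes$key %in% leukemic_keys

  query <- NULL
  if (mode == "standard") {
    sub <- subsample_repertoire(rep, config$subsample_depth, seed = seed)
    if (is_excluded(sub)) return(sub)
  } else {
    remainder <- exclude_clonotypes(rep, leukemic_keys)
    sub <- subsample_repertoire(remainder, config$subsample_depth, seed = seed)
    if (is_excluded(sub)) return(sub)
    if (length(leukemic_keys)) {
      li <- match(leukemic_keys, rep$clonotypes$key)
      query <- data.frame(key = leukemic_keys,
                          cdr3_aa = rep$clonotypes$cdr3_aa[li],
                          leukemic = TRUE, stringsAsFactors = FALSE)
    }
  }

  groups <- build_specificity_groups(sub, reference, config, query = query)

  calls <- lapply(leukemic_keys, function(k) {
    node <- match(k, groups$nodes$key)
    if (is.na(node)) {
      # standard mode: leukemic clone lost every read in the draw
      return(data.frame(sample_id = rep$sample_id, leukemic_key = k,
                        driven = NA, supporting_group_id = NA_integer_,
                        n_group_members = NA_integer_,
                        n_nonleukemic_partners = NA_integer_,
                        any_significant_group = NA,
                        mode = mode, subsample_seed = as.integer(seed),
                        stringsAsFactors = FALSE))
    }
    gid <- groups$nodes$group_id[node]
    grp <- groups$groups[groups$groups$group_id == gid, ]
    members <- which(groups$nodes$group_id == gid)
    n_nonleuk <- sum(!(groups$nodes$key[members] %in% leukemic_keys))
    driven <- isTRUE(grp$significant) &&
      grp$n_members >= config$min_group_size && n_nonleuk >= 1L
    any_sig <- any(groups$groups$significant &
                     groups$groups$n_members >= config$min_group_size)
    data.frame(sample_id = rep$sample_id, leukemic_key = k,
               driven = driven,
               supporting_group_id = if (driven) gid else NA_integer_,
               n_group_members = grp$n_members,
               n_nonleukemic_partners = n_nonleuk,
               any_significant_group = any_sig,
               mode = mode, subsample_seed = as.integer(seed),
               stringsAsFactors = FALSE)
  })
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), leukemic_key = character(),
               driven = logical(), supporting_group_id = integer(),
               n_group_members = integer(), n_nonleukemic_partners = integer(),
               any_significant_group = logical(), mode = character(),
               subsample_seed = integer(), stringsAsFactors = FALSE)

  structure(list(calls = calls, groups = groups, repertoire = sub),
            class = "tcrdrive_drive_calls")
}

#' @export
print.tcrdrive_drive_calls <- function(x, ...) {
  n <- nrow(x$calls)
  cat(sprintf("drive calls: %d leukemic clone(s), %d driven, %d indeterminate\n",
              n, sum(x$calls$driven, na.rm = TRUE), sum(is.na(x$calls$driven))))
  invisible(x)
}

#' Compare antigen-drive prevalence between cohorts
#'
#' One-sided Fisher exact test that the focal cohort (first row by
#' default) has a greater proportion of antigen-driven samples than each
#' other cohort.
#'
#' @param table data.frame with columns `cohort`, `n_samples`, `n_driven`.
#' @param focal Name of the focal cohort; defaults to the first row.
#' @return The input with per-comparison rows: `cohort`, `n_samples`,
#'   `n_driven`, `p_vs_focal` (NA for the focal cohort itself).
#' @export
compare_drive_prevalence <- function(table, focal = NULL) {
  need <- c("cohort", "n_samples", "n_driven")
  if (!all(need %in% names(table)))
    stop_tcrdrive("format_error", "table must have columns %s",
                  paste(need, collapse = ", "))
  if (nrow(table) < 2L)
    stop_tcrdrive("parameter_error", "need at least two cohorts")
  if (any(table$n_samples < 1L))
    stop_tcrdrive("parameter_error", "every cohort needs n_samples >= 1")
  if (any(table$n_driven > table$n_samples | table$n_driven < 0))
    stop_tcrdrive("validation_error", "n_driven must lie in [0, n_samples]")
  focal <- focal %||% table$cohort[1L]
  fi <- match(focal, table$cohort)
  if (is.na(fi))
    stop_tcrdrive("key_error", "focal cohort '%s' not in table", focal)

  table$p_vs_focal <- vapply(seq_len(nrow(table)), function(i) {
    if (i == fi) return(NA_real_)
    m <- matrix(c(table$n_driven[fi], table$n_samples[fi] - table$n_driven[fi],
                  table$n_driven[i], table$n_samples[i] - table$n_driven[i]),
                nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = "greater")$p.value
  }, numeric(1))
  table
}

#' Compare clone sizes between driven and non-driven clones
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-clone
#' frequencies split by drive label, with group medians. Mid-ranks are
#' used for ties; the null distribution is enumerated exactly (by rank-sum
#' convolution over the observed, possibly tied, rank multiset) when both
#' groups have at most 20 observations, and approximated normally (with
#' tie correction and continuity correction) above that.
#'
#' @param sizes Numeric vector of clone frequencies.
#' @param driven Logical vector parallel to `sizes`.
#' @return List with `statistic` (U for the driven group), `p_value`,
#'   `median_driven`, `median_not_driven`, `n_driven`, `n_not_driven`,
#'   `method`.
#' @export
compare_clone_sizes_by_drive <- function(sizes, driven) {
  stopifnot(length(sizes) == length(driven))
  keep <- !is.na(driven) & is.finite(sizes)
  x <- sizes[keep & driven]   # driven group
  y <- sizes[keep & !driven]
  if (length(x) == 0L || length(y) == 0L)
    stop_tcrdrive("parameter_error", "both drive groups must be non-empty")
  mw <- mann_whitney(x, y)
  list(statistic = mw$U, p_value = mw$p,
       median_driven = stats::median(x), median_not_driven = stats::median(y),
       n_driven = length(x), n_not_driven = length(y), method = mw$method)
}

# Two-sided Mann-Whitney with mid-ranks. Exact by enumeration of the
# rank-sum distribution over the observed rank multiset for small groups
# (handles ties exactly); wilcox.test's normal approximation otherwise.
mann_whitney <- function(x, y, exact_max = 20L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- exact_ranksum_p(r, n1, U)
    list(U = U, p = p, method = "exact")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value, method = "normal")
  }
}

# Exact two-sided p for the rank-sum statistic given the observed mid-rank
# multiset: dynamic-programming convolution over which of the n ranks go
# to group 1. Ranks are doubled to keep integer arithmetic with .5 ranks.
exact_ranksum_p <- function(r, n1, U_obs) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  total <- sum(r2)
  # dp[[k]][s+1] = number of k-subsets with doubled-rank sum s
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      nz <- which(dp[k, ] > 0)
      if (length(nz)) {
        tgt <- nz + v
        ok <- tgt <= maxs + 1L
        dp[k + 1L, tgt[ok]] <- dp[k + 1L, tgt[ok]] + dp[k, nz[ok]]
      }
    }
  }
  counts <- dp[n1 + 1L, ]
  sums2 <- which(counts > 0) - 1L          # doubled rank sums
  U_all <- sums2 / 2 - n1 * (n1 + 1) / 2   # corresponding U values
  w <- counts[counts > 0]
  EU <- sum(U_all * w) / sum(w)
  dev_obs <- abs(U_obs - EU) - 1e-9
  p <- sum(w[abs(U_all - EU) >= dev_obs]) / sum(w)
  min(1, p)
}
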