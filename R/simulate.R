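# Synthetic repertoires, cohorts and expression matrices with planted
# ground truth. Generators are pure functions of (parameters, seed).

# Interior amino-acid frequencies for simulated CDR3s: a fixed, documented
# bias with glycine/tyrosine/leucine-rich centres. Every letter of the
# default planted motif ("QRST") is kept rare so that the motif's
# background occurrence is rare by construction (~1e-5 per CDR3); planted
# enrichment must stand out against the reference, so this property is
# load-bearing for the planted-truth design, and background collisions are
# still counted into the truth record rather than assumed zero.
CDR3_AA_FREQ <- c(
  A = 0.080, C = 0.010, D = 0.050, E = 0.060, F = 0.035, G = 0.155,
  H = 0.015, I = 0.035, K = 0.025, L = 0.100, M = 0.010, N = 0.040,
  P = 0.050, Q = 0.020, R = 0.025, S = 0.060, T = 0.030, V = 0.055,
  W = 0.005, Y = 0.140
)

# Length law for simulated CDR3s: discretized normal, mean 14.5, sd 1.5,
# clipped to [8, 22].
sample_cdr3_lengths <- function(n) {
  pmin(pmax(round(stats::rnorm(n, mean = 14.5, sd = 1.5)), 8L), 22L)
}

# n random productive CDR3 beta sequences: conserved C ... F/W frame with
# biased interior residues. Not guaranteed distinct.
random_cdr3 <- function(n) {
  lens <- sample_cdr3_lengths(n)
  last <- sample(c("F", "W"), n, replace = TRUE, prob = c(0.9, 0.1))
  interior <- vapply(lens - 2L, function(m)
    paste(sample(names(CDR3_AA_FREQ), m, replace = TRUE,
                 prob = CDR3_AA_FREQ), collapse = ""), character(1))
  paste0("C", interior, last)
}

# n DISTINCT random CDR3s (resamples collisions).
random_cdr3_distinct <- function(n) {
  out <- unique(random_cdr3(n))
  while (length(out) < n) {
    out <- unique(c(out, random_cdr3(n - length(out) + 16L)))
  }
  out[seq_len(n)]
}

#' Generate a reference repertoire
#'
#' A background repertoire of `n` distinct productive CDR3 beta sequences
#' with uniform singleton counts, used as the enrichment reference for
#' specificity grouping (a synthetic stand-in for the bundled reference
#' sets of GLIPH-style tools, which are not redistributed). Lengths follow
#' a discretized normal (mean 14.5, sd 1.5, clipped to [8, 22]); sequences
#' are framed by the conserved C ... F/W residues with interior residues
#' drawn from a fixed biased amino-acid table.
#'
#' @param n Number of distinct CDR3s (>= 100, the enrichment guard).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `tcr_repertoire` with cohort label "reference".
#' @export
generate_reference_repertoire <- function(n, seed = 1L) {
  if (!is_count(n) || n < 100L)
    stop_tcrdrive("parameter_error",
                  "reference size must be >= 100 (enrichment guard), got %s", n)
  cdr3 <- with_seed(seed, random_cdr3_distinct(as.integer(n)))
  new_repertoire(
    data.frame(cdr3_aa = cdr3, read_count = 1L, productive = TRUE,
               stringsAsFactors = FALSE),
    sample_id = sprintf("reference_n%d_seed%d", n, as.integer(seed)),
    cohort_label = "reference", key_scheme = "cdr3aa")
}

#' Generate a sample repertoire with planted ground truth
#'
#' Simulates one patient-style repertoire: clone sizes follow a truncated
#' power law (`P(size >= s) ~ s^(1 - alpha)`, default `alpha = 2.5`)
#' scaled to the requested depth, emulating the oligoclonal-to-polyclonal
#' spectrum seen in leukemic repertoires. Optionally a leukemic clone is
#' planted at an exact target frequency (the observed immunodominant range
#' is 7-50% of the repertoire), and, when `driven = TRUE`, a specificity
#' group is planted: `group_size` non-leukemic partner clones receive the
#' planted motif at a random valid position of their trimmed CDR3 core,
#' and so does the leukemic clone. When `driven = FALSE` no motif is
#' planted and the leukemic CDR3 is guaranteed not to contain it.
#'
#' @param n_clonotypes Number of non-leukemic clonotypes drawn.
#' @param depth Total read depth of the generated repertoire.
#' @param alpha Power-law exponent of the clone-size law.
#' @param leukemic_freq Target frequency of the planted leukemic clone in
#'   `[0.07, 0.50]`, or `NA` for no leukemic clone.
#' @param driven Plant a motif-sharing specificity group linking the
#'   leukemic clone to `group_size` partners?
#' @param group_size Number of non-leukemic partner clones carrying the
#'   motif.
#' @param partner_freq Target frequency of each partner clone (so partners
#'   survive rarefaction).
#' @param motif Planted motif (default "QRST", rare under the generator's
#'   amino-acid table; background collisions are possible and measured by
#'   the truth record, not assumed absent).
#' @param config A [pipeline_config()] (trim geometry for motif planting).
#' @param seed Integer seed.
#' @param sample_id,cohort_label,sort_label Metadata for the repertoire.
#' @return List with `repertoire` (a `tcr_repertoire`) and `truth` (list:
#'   generator parameters, `leukemic_key`, `driven`, `planted_motif`,
#'   `group_keys`, `n_background_motif` — the number of non-planted CDR3s
#'   that contain the motif by chance).
#' @export
generate_sample_repertoire <- function(n_clonotypes = 2000L,
                                       depth = 60000L,
                                       alpha = 2.5,
                                       leukemic_freq = 0.20,
                                       driven = TRUE,
                                       group_size = 4L,
                                       partner_freq = 0.005,
                                       motif = "QRST",
                                       config = NULL,
                                       seed = 1L,
                                       sample_id = NULL,
                                       cohort_label = "synthetic",
                                       sort_label = "CD8") {
  config <- as_config(config)
  if (!is.na(leukemic_freq)) {
    if (leukemic_freq < 0.07 || leukemic_freq > 0.50)
      stop_tcrdrive("parameter_error",
                    "leukemic_freq must lie in [0.07, 0.50] (observed immunodominant range)")
    if (round(leukemic_freq * depth) < 1)
      stop_tcrdrive("parameter_error",
                    "depth %d too small to realize leukemic frequency %.3f as >= 1 read",
                    depth, leukemic_freq)
  }
  if (driven && is.na(leukemic_freq))
    stop_tcrdrive("parameter_error", "a driven sample needs a leukemic clone")
  sample_id <- sample_id %||% sprintf("sim_seed%d", as.integer(seed))

  res <- with_seed(seed, {
    n <- as.integer(n_clonotypes)
    # truncated discrete power law by inversion: s = floor(u^(-1/(alpha-1)))
    u <- stats::runif(n)
    sizes <- pmin(floor(u^(-1 / (alpha - 1))), depth)

    leuk_reads <- if (is.na(leukemic_freq)) 0L else
      as.integer(round(leukemic_freq * depth))
    n_partners <- if (driven) as.integer(group_size) else 0L
    partner_reads <- if (n_partners > 0L)
      rep(max(1L, as.integer(round(partner_freq * depth))), n_partners)
    else integer()

    # scale the power-law tail onto the remaining reads (largest remainder)
    rest <- depth - leuk_reads - sum(partner_reads)
    if (rest < n) stop_tcrdrive("parameter_error",
                                "depth too small for %d background clonotypes", n)
    share <- sizes / sum(sizes) * rest
    counts <- floor(share)
    counts <- counts + as.integer(seq_len(n) %in%
      order(share - counts, decreasing = TRUE)[seq_len(rest - sum(counts))])
    keep <- counts >= 1L
    counts <- counts[keep]

    cdr3 <- random_cdr3_distinct(length(counts) + n_partners +
                                   (!is.na(leukemic_freq)))
    bg_cdr3 <- cdr3[seq_along(counts)]
    partner_cdr3 <- if (n_partners > 0L)
      cdr3[length(counts) + seq_len(n_partners)] else character()
    leuk_cdr3 <- if (!is.na(leukemic_freq)) cdr3[length(cdr3)] else NA_character_

    plant <- function(s, motif) {
      # overwrite a random window of the trimmed core with the motif
      L <- nchar(s); k <- nchar(motif)
      lo <- config$cdr3_trim[1] + 1L
      hi <- L - config$cdr3_trim[2] - k + 1L
      if (hi < lo) {  # core too short: lengthen by inserting the motif
        return(paste0(substr(s, 1L, lo - 1L), motif,
                      substr(s, lo, L)))
      }
      pos <- sample(lo:hi, 1L)
      paste0(substr(s, 1L, pos - 1L), motif, substr(s, pos + k, L))
    }
    if (driven) {
      partner_cdr3 <- vapply(partner_cdr3, plant, character(1), motif = motif,
                             USE.NAMES = FALSE)
      leuk_cdr3 <- plant(leuk_cdr3, motif)
    } else if (!is.na(leukemic_freq)) {
      while (grepl(motif, leuk_cdr3, fixed = TRUE)) {
        leuk_cdr3 <- random_cdr3(1L)
      }
    }

    df <- data.frame(
      cdr3_aa = c(leuk_cdr3[!is.na(leuk_cdr3)], partner_cdr3, bg_cdr3),
      read_count = c(if (leuk_reads > 0L) leuk_reads else integer(),
                     partner_reads, counts),
      productive = TRUE, stringsAsFactors = FALSE)
    df$leukemic <- c(if (leuk_reads > 0L) TRUE else logical(),
                     rep(FALSE, length(partner_reads) + length(counts)))
    list(df = df, leuk_cdr3 = leuk_cdr3, partner_cdr3 = partner_cdr3,
         bg_cdr3 = bg_cdr3)
  })

  rep <- new_repertoire(res$df, sample_id = sample_id,
                        cohort_label = cohort_label, sort_label = sort_label,
                        key_scheme = "cdr3aa")
  truth <- list(
    sample_id = sample_id,
    n_clonotypes = n_clonotypes, depth = depth, alpha = alpha,
    leukemic_freq = leukemic_freq, driven = driven,
    planted_motif = motif, seed = as.integer(seed),
    leukemic_key = if (!is.na(leukemic_freq)) res$leuk_cdr3 else NA_character_,
    group_keys = res$partner_cdr3,
    n_background_motif = sum(grepl(motif, res$bg_cdr3, fixed = TRUE))
  )
  list(repertoire = rep, truth = truth)
}

#' Generate a synthetic cohort with planted drive truth
#'
#' `n_samples` repertoires from [generate_sample_repertoire()], of which
#' `round(n_samples * drive_fraction)` are planted antigen-driven. Each
#' sample gets an independent seed derived from the master seed, a
#' leukemic frequency drawn uniformly from `[0.07, 0.50]`, and shares the
#' supplied reference for later enrichment testing.
#'
#' @param n_samples Number of samples (>= 2).
#' @param drive_fraction Fraction of samples planted driven, in `[0, 1]`.
#' @param seed Master seed.
#' @param cohort_label Label stamped on every sample.
#' @param ... Further arguments passed to [generate_sample_repertoire()].
#' @return List with `samples` (list of `tcr_repertoire`) and `truth`
#'   (data.frame: `sample_id`, `driven`, `leukemic_key`, `leukemic_freq`,
#'   `planted_motif`, `seed`).
#' @export
generate_cohort <- function(n_samples = 40L, drive_fraction = 0.5,
                            seed = 1L, cohort_label = "synthetic", ...) {
  if (!is_count(n_samples) || n_samples < 2L)
    stop_tcrdrive("parameter_error", "n_samples must be >= 2")
  if (drive_fraction < 0 || drive_fraction > 1)
    stop_tcrdrive("parameter_error", "drive_fraction must lie in [0, 1]")
  n_driven <- round(n_samples * drive_fraction)
  driven_flags <- rep(c(TRUE, FALSE), c(n_driven, n_samples - n_driven))
  seeds <- derive_seeds(seed, n_samples + 1L)
  freqs <- with_seed(seeds[n_samples + 1L],
                     stats::runif(n_samples, 0.07, 0.50))

  out <- lapply(seq_len(n_samples), function(i) {
    generate_sample_repertoire(
      leukemic_freq = freqs[i], driven = driven_flags[i],
      seed = seeds[i], sample_id = sprintf("%s_%02d", cohort_label, i),
      cohort_label = cohort_label, ...)
  })
  truth <- do.call(rbind, lapply(out, function(o)
    data.frame(sample_id = o$truth$sample_id, driven = o$truth$driven,
               leukemic_key = o$truth$leukemic_key,
               leukemic_freq = o$truth$leukemic_freq,
               planted_motif = o$truth$planted_motif,
               seed = o$truth$seed, stringsAsFactors = FALSE)))
  list(samples = lapply(out, `[[`, "repertoire"), truth = truth)
}

#' Generate an expression matrix with a planted gene-set shift
#'
#' Baseline per-gene mean expression is drawn from a log-normal law and
#' per-cell values from a normal around it (clipped at zero), emulating a
#' log-normalized genes x cells matrix. The planted gene set is shifted by
#' `+delta` (log scale) in a marked subset of cells. This is the test bed
#' for [module_score()] and [de_test()]: the marked subset's mean module
#' score recovers `delta` and planted genes are differentially expressed.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param planted_genes Character vector of planted gene names; must be a
#'   subset of the generated gene names `gene0001...` (or supply indices
#'   via `planted_idx`).
#' @param planted_idx Integer indices of planted genes (alternative to
#'   `planted_genes`).
#' @param delta Log-scale shift added in the marked subset.
#' @param subset_fraction Fraction of cells marked, in (0, 1).
#' @param baseline_sd Per-cell noise standard deviation.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x cells), `labels` (logical, TRUE for
#'   marked cells) and `planted_genes`.
#' @export
generate_expression_matrix <- function(n_genes = 1000L, n_cells = 500L,
                                       planted_idx = 1:10,
                                       planted_genes = NULL,
                                       delta = 1.0, subset_fraction = 0.2,
                                       baseline_sd = 0.5, seed = 1L) {
  if (subset_fraction <= 0 || subset_fraction >= 1)
    stop_tcrdrive("parameter_error", "subset_fraction must lie in (0, 1)")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (!is.null(planted_genes)) {
    planted_idx <- match(planted_genes, genes)
    if (anyNA(planted_idx))
      stop_tcrdrive("key_error", "planted gene(s) not among generated genes")
  }
  if (any(planted_idx < 1L | planted_idx > n_genes))
    stop_tcrdrive("parameter_error", "planted_idx out of range")

  with_seed(seed, {
    mu <- stats::rlnorm(n_genes, meanlog = 1.2, sdlog = 0.4)
    m <- matrix(stats::rnorm(n_genes * n_cells, mean = mu, sd = baseline_sd),
                nrow = n_genes)
    n_marked <- max(1L, round(n_cells * subset_fraction))
    marked <- sample.int(n_cells, n_marked)
    labels <- seq_len(n_cells) %in% marked
    m[planted_idx, labels] <- m[planted_idx, labels] + delta
    m[m < 0] <- 0
    rownames(m) <- genes
    colnames(m) <- sprintf("cell%04d", seq_len(n_cells))
    list(matrix = m, labels = labels, planted_genes = genes[planted_idx])
  })
}
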