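# Gene-set scoring of expression matrices and a simple DE test.
# Matrices are genes x cells (or genes x samples), log-normalized,
# non-negative; normalization itself is a precondition, not performed here.

check_matrix <- function(mat) {
  if (!is.matrix(mat) && !inherits(mat, "Matrix"))
    stop_tcrdrive("parameter_error", "expression input must be a matrix (genes x cells)")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_tcrdrive("validation_error", "matrix needs unique gene identifiers as rownames")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop_tcrdrive("validation_error", "matrix needs unique cell/sample identifiers as colnames")
  vals <- if (inherits(mat, "Matrix")) mat@x else mat
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_tcrdrive("validation_error", "expression values must be finite and >= 0")
  invisible(mat)
}

#' Bundled gene sets
#'
#' The three gene sets packaged with tcrdrive:
#' \describe{
#'   \item{cytotoxicity}{GZMA, GZMH, GZMM, PRF1, GNLY — the cytotoxic
#'     effector signature used to score T/NK cells.}
#'   \item{hla_ii}{14 HLA class II genes (antigen-presentation score).}
#'   \item{scavenger}{27 scavenger-receptor (SCAR family) genes
#'     (monocyte scavenging score).}
#' }
#' Hallmark pathway sets (e.g. IFN-gamma response, TNFA signalling via
#' NF-kB) are licensed collections and must be supplied by the user as GMT
#' or two-column TSV files; see [read_gene_sets()].
#'
#' @return Named list of character vectors.
#' @export
packaged_gene_sets <- function() {
  list(
    cytotoxicity = c("GZMA", "GZMH", "GZMM", "PRF1", "GNLY"),
    hla_ii = c("HLA-DMA", "HLA-DMB", "HLA-DOA", "HLA-DOB", "HLA-DPA1",
               "HLA-DPB1", "HLA-DQA1", "HLA-DQB1", "HLA-DQB1-AS1",
               "HLA-DQA2", "HLA-DQB2", "HLA-DRA", "HLA-DRB1", "HLA-DRB5"),
    scavenger = c("CD14", "CD207", "CD209", "LY75", "MRC1", "MSR1", "MARCO",
                  "SCARA3", "COLEC12", "SCARA5", "SCARB1", "SCARB2", "CD36",
                  "CD68", "OLR1", "CLEC7A", "SCARF1", "SCARF2", "MEGF10",
                  "CXCL16", "STAB2", "STAB1", "CD163", "CD163L1", "AGER",
                  "SSC4D", "SSC5D")
  )
}

#' Read gene sets from GMT or two-column TSV
#'
#' @param path GMT file (set name, description, genes...) or a headerless
#'   two-column TSV (set name, gene).
#' @param format `"gmt"` or `"tsv"`; guessed from the extension by default.
#' @return Named list of character vectors (duplicates removed).
#' @export
read_gene_sets <- function(path, format = NULL) {
  if (!file.exists(path))
    stop_tcrdrive("format_error", "file not found: %s", path)
  format <- format %||% if (grepl("\\.gmt$", path, ignore.case = TRUE))
    "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)][p[-(1:2)] != ""]))
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    sets
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    lapply(split(df[[2L]], df[[1L]]), unique)
  }
}

#' Expression-matched module score
#'
#' Per-cell gene-set score in the Tirosh scheme: the mean expression of the
#' set genes minus the mean expression of a control gene pool matched on
#' average expression. Genes are binned into `score_bins` (default 24)
#' equal-frequency bins by their mean expression across cells; for every
#' set gene, `n_control_genes` (default 100) control genes are drawn
#' without replacement from its bin (the whole bin when it is smaller) and
#' pooled. The subtraction removes cell-level technical covariation, so a
#' random gene set scores ~0.
#'
#' Set genes absent from the matrix are dropped with a warning.
#'
#' @param mat Genes x cells matrix of log-normalized expression with gene
#'   rownames and cell colnames.
#' @param genes Character vector of set genes (or a single element of
#'   [packaged_gene_sets()]).
#' @param config A [pipeline_config()] (`score_bins`, `n_control_genes`).
#' @param seed Integer seed for the control draw; identical seeds give
#'   bit-identical scores.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(mat, genes, config = NULL, seed = NULL) {
  config <- as_config(config)
  check_matrix(mat)
  seed <- seed %||% config$rng_seed
  if (nrow(mat) < config$score_bins)
    stop_tcrdrive("parameter_error",
                  "matrix has %d genes but score_bins = %d", nrow(mat),
                  config$score_bins)
  present <- intersect(unique(genes), rownames(mat))
  missing <- setdiff(unique(genes), present)
  if (length(missing))
    warning(sprintf("%d gene-set gene(s) absent from matrix and dropped: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  if (length(present) == 0L)
    stop_tcrdrive("parameter_error", "no gene-set gene present in the matrix")

  avg <- Matrix::rowMeans(mat)
  # equal-frequency bins on mean expression; random ties broken
  # deterministically by gene order
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = config$score_bins, labels = FALSE)
  names(bins) <- rownames(mat)

  controls <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], g)
      if (length(pool) <= config$n_control_genes) pool
      else sample(pool, config$n_control_genes)
    }), use.names = FALSE)
  })

  set_mean <- Matrix::colMeans(mat[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(mat[controls, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Geometric-mean gene-set score
#'
#' Per-sample bulk score: `exp(mean(log(x + eps))) - eps` over the set
#' genes, with `eps = pseudocount` (default 1). Unlike [module_score()],
#' every set gene must be present — a five-gene score silently shrinking
#' to four would change its meaning — so missing genes are an error.
#'
#' @param mat Genes x samples matrix (non-negative expression).
#' @param genes Character vector of set genes; all must be present.
#' @param pseudocount Offset `eps` (>= 0).
#' @return Named numeric vector of per-sample scores.
#' @export
geometric_mean_score <- function(mat, genes, pseudocount = 1) {
  check_matrix(mat)
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop_tcrdrive("parameter_error", "pseudocount must be non-negative")
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop_tcrdrive("key_error", "gene(s) absent from matrix: %s",
                  paste(missing, collapse = ", "))
  sub <- as.matrix(mat[genes, , drop = FALSE])
  exp(colMeans(log(sub + pseudocount))) - pseudocount
}

#' Per-gene two-group differential expression
#'
#' Welch two-sided t-test per gene between two groups of cells/samples,
#' with the log2 fold-change taken as the difference of group means on the
#' log scale (natural-log input rescaled to log2). P-values are adjusted
#' over the number of *tested* genes (genes with zero pooled variance are
#' reported untested with `p = NA`). A rank-based companion
#' (`test = "wilcox"`, Mann-Whitney) is available for the variant analyses
#' that pair the rank test with Benjamini-Hochberg adjustment.
#'
#' @param mat Genes x cells matrix of log-normalized expression.
#' @param group_labels Vector of two distinct labels, one per column.
#' @param adjust `"bonferroni"` (default) or `"bh"`.
#' @param test `"t"` (Welch) or `"wilcox"`.
#' @param log_base Base of the input log-normalization, used to rescale
#'   the fold-change to log2 (default `exp(1)`).
#' @return data.frame: `gene`, `log2_fc` (group1 minus group2), `p`,
#'   `p_adjusted`, `adjust_method`, sorted by adjusted then raw p.
#' @export
de_test <- function(mat, group_labels, adjust = c("bonferroni", "bh"),
                    test = c("t", "wilcox"), log_base = exp(1)) {
  adjust <- match.arg(adjust)
  test <- match.arg(test)
  check_matrix(mat)
  if (length(group_labels) != ncol(mat))
    stop_tcrdrive("parameter_error", "one group label per column required")
  lv <- unique(group_labels)
  if (length(lv) != 2L)
    stop_tcrdrive("parameter_error", "exactly two groups required (got %d)",
                  length(lv))
  g1 <- group_labels == lv[1L]
  g2 <- group_labels == lv[2L]
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop_tcrdrive("parameter_error", "each group needs >= 2 observations")

  m <- as.matrix(mat)
  m1 <- m[, g1, drop = FALSE]
  m2 <- m[, g2, drop = FALSE]
  mean1 <- rowMeans(m1); mean2 <- rowMeans(m2)
  v1 <- apply(m1, 1L, stats::var); v2 <- apply(m2, 1L, stats::var)
  testable <- (v1 + v2) > 0

  p <- rep(NA_real_, nrow(m))
  if (test == "t") {
    n1 <- sum(g1); n2 <- sum(g2)
    se2 <- v1 / n1 + v2 / n2
    tt <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p[testable] <- 2 * stats::pt(-abs(tt[testable]), df[testable])
  } else {
    p[testable] <- vapply(which(testable), function(i)
      suppressWarnings(stats::wilcox.test(m1[i, ], m2[i, ])$p.value),
      numeric(1))
  }
  n_tested <- sum(testable)
  if (n_tested == 0L)
    stop_tcrdrive("parameter_error", "no gene with nonzero pooled variance to test")

  padj <- rep(NA_real_, nrow(m))
  padj[testable] <- stats::p.adjust(
    p[testable], method = if (adjust == "bh") "BH" else "bonferroni")

  out <- data.frame(gene = rownames(m),
                    log2_fc = (mean1 - mean2) * log2(log_base),
                    p = p, p_adjusted = padj,
                    adjust_method = adjust,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, out$p, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname de_test
#' @export
de_ttest <- function(mat, group_labels, adjust = c("bonferroni", "bh"),
                     log_base = exp(1)) {
  de_test(mat, group_labels, adjust = adjust, test = "t", log_base = log_base)
}

#' Read an expression matrix
#'
#' Either an MTX triplet (`matrix.mtx` plus gene and barcode TSVs, genes in
#' rows) or a dense TSV with gene rownames and cell/sample column names.
#'
#' @param path Path to `matrix.mtx` (with `genes_path`/`cells_path`) or to
#'   a dense TSV.
#' @param format `"mtx"` or `"dense"`; guessed from the extension.
#' @param genes_path,cells_path Companion files for the MTX triplet; first
#'   column is used.
#' @return Genes x cells matrix (dense, base R).
#' @export
read_expression_matrix <- function(path, format = NULL,
                                   genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path))
    stop_tcrdrive("format_error", "file not found: %s", path)
  format <- format %||% if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(cells_path))
      stop_tcrdrive("parameter_error", "MTX input needs genes_path and cells_path")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- utils::read.delim(genes_path, header = FALSE,
                                     stringsAsFactors = FALSE)[[1L]]
    colnames(m) <- utils::read.delim(cells_path, header = FALSE,
                                     stringsAsFactors = FALSE)[[1L]]
    m
  } else {
    df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  }
}
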