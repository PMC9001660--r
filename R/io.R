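# Readers and writers for the repertoire table dialects.

# Productivity fallback when the input has no flag column: a CDR3 is
# considered productive iff it is a plain 20-letter amino-acid string that
# starts with the conserved C and ends with F or W, with no stop ('*') or
# frameshift ('_') marks. Standard AIRR convention.
productive_fallback <- function(cdr3) {
  !grepl("[*_]", cdr3, fixed = FALSE) &
    grepl(sprintf("^C[%s]*[FW]$", paste(AA20, collapse = "")), cdr3)
}

first_column <- function(df, candidates, path, required = TRUE) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0L) {
    if (required)
      stop_tcrdrive("format_error",
                    "file '%s' lacks required column (one of: %s)",
                    path, paste(candidates, collapse = ", "))
    return(NULL)
  }
  df[[hit[[1L]]]]
}

#' Read a TCR repertoire file
#'
#' Reads one sample's rearrangement table in one of three dialects and
#' returns a validated, aggregated [new_repertoire()] object with
#' frequencies recomputed from counts.
#'
#' Supported formats:
#' \describe{
#'   \item{`airr`}{AIRR-C rearrangement TSV. Uses `junction_aa`, `v_call`,
#'     `j_call`, `duplicate_count` and `productive`; the read unit is the
#'     duplicate count.}
#'   \item{`immunoseq`}{immunoSEQ-style export TSV. Accepts the common
#'     column spellings (`amino_acid`/`aminoAcid`, `templates`/`count
#'     (templates/reads)`/`count`, `v_gene`/`vGeneName`, `frame_type`/
#'     `sequenceStatus`); the read unit is the template count. Rows whose
#'     frame type is not "In" are marked non-productive.}
#'   \item{`tenx_contigs`}{10x Genomics `filtered_contig_annotations.csv`.
#'     Cells are aggregated into clonotypes via
#'     [aggregate_sc_clonotypes()]; the read unit is the cell count.}
#'   \item{`canonical`}{This package's own output format (see
#'     [write_repertoire()]).}
#' }
#'
#' When the dialect has no productivity flag the CDR3-based fallback rule is
#' applied (C...F/W pattern, no `*` or `_`).
#'
#' @param path File path.
#' @param format One of `"airr"`, `"immunoseq"`, `"tenx_contigs"`,
#'   `"canonical"`.
#' @param key_scheme Clonotype key scheme, see [new_repertoire()].
#' @param sample_id Sample identifier; defaults to the file name.
#' @param cohort_label,sort_label Optional metadata tags.
#' @return A `tcr_repertoire`.
#' @export
read_repertoire <- function(path,
                            format = c("airr", "immunoseq", "tenx_contigs",
                                       "canonical"),
                            key_scheme = c("cdr3aa", "cdr3aa_v", "paired"),
                            sample_id = NULL,
                            cohort_label = NA_character_,
                            sort_label = NA_character_) {
  format <- match.arg(format)
  key_scheme <- match.arg(key_scheme)
  if (!file.exists(path))
    stop_tcrdrive("format_error", "file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  sep <- if (format == "tenx_contigs") "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L)
    stop_tcrdrive("empty_repertoire", "file '%s' contains no rows", path)

  clono <- switch(format,
    airr = parse_airr(df, path),
    immunoseq = parse_immunoseq(df, path),
    tenx_contigs = return(aggregate_sc_clonotypes(
      df, sample_id = sample_id, cohort_label = cohort_label,
      sort_label = sort_label)),
    canonical = parse_canonical(df, path)
  )
  new_repertoire(clono, sample_id = sample_id, cohort_label = cohort_label,
                 sort_label = sort_label, key_scheme = key_scheme)
}

parse_airr <- function(df, path) {
  cdr3 <- first_column(df, "junction_aa", path)
  count <- first_column(df, "duplicate_count", path)
  prod <- first_column(df, "productive", path)
  data.frame(
    cdr3_aa = cdr3,
    v_call = first_column(df, "v_call", path),
    j_call = first_column(df, "j_call", path),
    read_count = as.integer(count),
    productive = parse_logical(prod),
    stringsAsFactors = FALSE
  )
}

parse_immunoseq <- function(df, path) {
  cdr3 <- first_column(df, c("amino_acid", "aminoAcid"), path)
  count <- first_column(df, c("templates", "count (templates/reads)",
                              "count", "reads"), path)
  frame <- first_column(df, c("frame_type", "sequenceStatus"), path,
                        required = FALSE)
  prod <- if (is.null(frame)) productive_fallback(cdr3) else frame %in% "In"
  data.frame(
    cdr3_aa = cdr3,
    v_call = first_column(df, c("v_gene", "vGeneName"), path, required = FALSE) %||%
      NA_character_,
    j_call = first_column(df, c("j_gene", "jGeneName"), path, required = FALSE) %||%
      NA_character_,
    read_count = as.integer(count),
    productive = prod,
    stringsAsFactors = FALSE
  )
}

parse_canonical <- function(df, path) {
  for (col in c("cdr3_aa", "read_count"))
    if (!col %in% names(df))
      stop_tcrdrive("format_error", "file '%s' lacks required column %s", path, col)
  df
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("t", "true", "1", "yes")
}

#' Aggregate single-cell V(D)J contigs into clonotypes
#'
#' Implements the paired-chain clone definition used for scRNA+TCRab data:
#' a clone is the exact CDR3 amino-acid sequence of both chains when the
#' alpha chain is available, otherwise the beta-chain CDR3 alone. Only
#' productive contigs are considered, and ambiguous cells carrying more
#' than one productive TRA or more than one productive TRB chain are
#' removed before aggregation. The clonotype read count is the number of
#' cells sharing the key.
#'
#' @param contigs data.frame with columns `barcode`, `chain`, `cdr3` (or
#'   `cdr3_aa`) and `productive`; typically a parsed
#'   `filtered_contig_annotations.csv`.
#' @param sample_id,cohort_label,sort_label Metadata passed through.
#' @return A `tcr_repertoire` keyed by the paired scheme. The number of
#'   dropped ambiguous cells is available as attribute `n_ambiguous_cells`,
#'   chainless (no productive TRB) cells as `n_chainless_cells`.
#' @export
aggregate_sc_clonotypes <- function(contigs, sample_id = "sample",
                                    cohort_label = NA_character_,
                                    sort_label = NA_character_) {
  for (col in c("barcode", "chain"))
    if (!col %in% names(contigs))
      stop_tcrdrive("format_error", "contig table lacks required column %s", col)
  cdr3 <- first_column(contigs, c("cdr3", "cdr3_aa"), "contig table")
  prod <- parse_logical(first_column(contigs, "productive", "contig table"))

  keep <- prod & contigs$chain %in% c("TRA", "TRB") & !is.na(cdr3) & cdr3 != ""
  bc <- contigs$barcode[keep]
  chain <- contigs$chain[keep]
  cdr3 <- cdr3[keep]

  n_cells_in <- length(unique(contigs$barcode))
  # Ambiguous: >1 productive TRA or >1 productive TRB in one cell.
  tra_per_cell <- table(bc[chain == "TRA"])
  trb_per_cell <- table(bc[chain == "TRB"])
  ambiguous <- union(names(tra_per_cell)[tra_per_cell > 1L],
                     names(trb_per_cell)[trb_per_cell > 1L])
  ok <- !(bc %in% ambiguous)
  bc <- bc[ok]; chain <- chain[ok]; cdr3 <- cdr3[ok]

  beta <- cdr3[chain == "TRB"]
  names(beta) <- bc[chain == "TRB"]
  alpha <- cdr3[chain == "TRA"]
  names(alpha) <- bc[chain == "TRA"]

  cells <- names(beta)  # a cell needs a productive TRB to define a clone
  if (length(cells) == 0L)
    stop_tcrdrive("empty_repertoire", "no cell with a productive TRB chain")
  cell_alpha <- alpha[match(cells, names(alpha))]

  key <- ifelse(is.na(cell_alpha), beta[cells],
                paste(beta[cells], cell_alpha, sep = "|"))
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(agg) <- c("key", "read_count")
  idx <- match(agg$key, key)
  agg$cdr3_aa <- unname(beta[cells][idx])
  agg$cdr3_aa_alpha <- unname(cell_alpha[idx])
  agg$productive <- TRUE

  rep <- new_repertoire(agg, sample_id = sample_id,
                        cohort_label = cohort_label, sort_label = sort_label,
                        key_scheme = "paired")
  attr(rep, "n_ambiguous_cells") <- length(ambiguous)
  attr(rep, "n_chainless_cells") <- n_cells_in - length(ambiguous) - length(cells)
  rep
}

#' Write a repertoire in the canonical TSV format
#'
#' Tab-separated, UTF-8, header row, '.' decimal separator; columns
#' `sample_id`, `key`, `cdr3_aa`, `cdr3_aa_alpha`, `v_call`, `j_call`,
#' `read_count`, `frequency`, `productive`, `leukemic`. Reading the file
#' back with `read_repertoire(format = "canonical")` reproduces keys,
#' counts and frequencies exactly.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  validate_repertoire(rep)
  df <- rep$clonotypes
  out <- data.frame(sample_id = rep$sample_id,
                    key = df$key, cdr3_aa = df$cdr3_aa,
                    cdr3_aa_alpha = df$cdr3_aa_alpha,
                    v_call = df$v_call, j_call = df$j_call,
                    read_count = df$read_count,
                    frequency = format(df$frequency, digits = 17),
                    productive = df$productive, leukemic = df$leukemic,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
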