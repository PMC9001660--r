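# Internal helpers shared across the package.

# 20 standard amino acids, one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish error kinds programmatically.
stop_tcrdrive <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("tcrdrive_", class), "tcrdrive_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a private RNG stream, restoring global RNG state.
# All stochastic operations in the package route through this so results
# are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive n child seeds from a master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Byte-order (locale-independent) ordering for character columns.
order_stable <- function(...) order(..., method = "radix")

# Canonical TSV writer: UTF-8, tab-separated, header, '.' decimal, no quotes.
write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

#' Box-plot summary statistics
#'
#' Five-number summary used for report output: median, interquartile range
#' (IQR) and whiskers extending to the most extreme observation within
#' 1.5 x IQR of the box.
#'
#' @param x Numeric vector.
#' @return Named list with `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n`.
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_tcrdrive("parameter_error", "no finite values")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = lo, whisker_high = hi, n = length(x))
}
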