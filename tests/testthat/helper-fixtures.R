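# Shared fixtures and independent oracles for the test suite.

make_rep <- function(counts, cdr3 = NULL, productive = TRUE, v = NULL,
                     sample_id = "s1", key_scheme = "cdr3aa", ...) {
  n <- length(counts)
  cdr3 <- cdr3 %||% sprintf("CASS%sPRGQETQYF", strrep("A", seq_len(n)))
  df <- data.frame(cdr3_aa = cdr3, read_count = counts,
                   productive = productive, stringsAsFactors = FALSE)
  if (!is.null(v)) df$v_call <- v
  new_repertoire(df, sample_id = sample_id, key_scheme = key_scheme, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Encode integers as 3-letter amino-acid tags (base-20) for unique,
# alphabet-valid fixture CDR3s.
aa_tag <- function(i, width = 3L) {
  alph <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(i, function(x) {
    d <- integer(width)
    for (k in seq_len(width)) {
      d[k] <- x %% 20L
      x <- x %/% 20L
    }
    paste(alph[rev(d) + 1L], collapse = "")
  }, character(1))
}

# Independent one-sided Fisher oracle: brute-force hypergeometric tail by
# explicit binomial-coefficient enumeration over the 2x2 table
# [(a, A-a), (b, B-b)] with fixed margins, alternative "greater".
fisher_oracle <- function(a, A, b, B) {
  K <- a + b          # marked items
  N <- A + B          # total items
  ks <- max(0, K - B):min(K, A)
  probs <- choose(K, ks) * choose(N - K, A - ks) / choose(N, A)
  sum(probs[ks >= a])
}

# Brute-force global-pair oracle: O(n^2) character-wise comparison.
global_pairs_oracle <- function(cdr3s, trim = c(3, 2), hamming_max = 1) {
  out <- list()
  core <- function(s) {
    n <- nchar(s)
    if (n - trim[1] - trim[2] < 1) return("")
    substr(s, trim[1] + 1, n - trim[2])
  }
  cores <- vapply(cdr3s, core, character(1), USE.NAMES = FALSE)
  chars <- strsplit(cores, "")
  for (i in seq_along(cdr3s)) {
    for (j in seq_along(cdr3s)) {
      if (j <= i) next
      if (nchar(cdr3s[i]) != nchar(cdr3s[j])) next
      if (cores[i] == "" || cores[j] == "") next
      d <- sum(chars[[i]] != chars[[j]])
      if (d <= hamming_max) out[[length(out) + 1]] <- c(i, j, d)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      distance = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], distance = m[, 3])
}

# Independent Welch t-test oracle (two-sided).
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(tt), df)
}

# Exhaustive two-sided Mann-Whitney oracle with mid-ranks: enumerates all
# choose(n1+n2, n1) assignments of the pooled observations to group 1.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(length(pool), n1)
  U_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  EU <- mean(U_all)
  mean(abs(U_all - EU) >= abs(U_obs - EU) - 1e-9)
}

# Write a tiny AIRR rearrangement TSV and return its path.
write_airr_fixture <- function(cdr3, count, productive = TRUE,
                               v = "TRBV19*01", j = "TRBJ2-1*01") {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(junction_aa = cdr3, v_call = v, j_call = j,
                   duplicate_count = count,
                   productive = ifelse(productive, "T", "F"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# n mutually dissimilar background CDR3s drawn from the same length and
# amino-acid law as the reference, so no background motif is enriched.
bg_cdr3s <- function(n, seed = 1234) {
  generate_reference_repertoire(max(100L, n), seed = seed)$clonotypes$cdr3_aa[seq_len(n)]
}

ref_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_reference_repertoire(2000, seed = 42)
    cache
  }
})
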