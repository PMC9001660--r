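test_that("module score is zero on a constant matrix and seed-deterministic", {
  m <- matrix(3, nrow = 50, ncol = 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20)))
  s <- module_score(m, c("g01", "g02"), pipeline_config(score_bins = 5L),
                    seed = 1)
  expect_equal(unname(s), rep(0, 20))

  sim <- generate_expression_matrix(n_genes = 200, n_cells = 50, seed = 3)
  cfg <- pipeline_config(score_bins = 10L, n_control_genes = 5L)
  a <- module_score(sim$matrix, sim$planted_genes, cfg, seed = 7)
  b <- module_score(sim$matrix, sim$planted_genes, cfg, seed = 7)
  expect_identical(a, b)
  c2 <- module_score(sim$matrix, sim$planted_genes, cfg, seed = 8)
  expect_false(identical(a, c2))
})

test_that("module score recovers a planted shift and is null for random sets", {
  delta <- 1.0
  sim <- generate_expression_matrix(n_genes = 1000, n_cells = 500,
                                    planted_idx = 1:10, delta = delta,
                                    subset_fraction = 0.2, seed = 11)
  s <- module_score(sim$matrix, sim$planted_genes, seed = 5)
  diff <- mean(s[sim$labels]) - mean(s[!sim$labels])
  # within 3x a Monte-Carlo SE of the score difference
  se <- sqrt(var(s[sim$labels]) / sum(sim$labels) +
               var(s[!sim$labels]) / sum(!sim$labels))
  expect_lt(abs(diff - delta), 3 * se + 0.05)

  # random matched gene set: mean score ~ 0, averaged over seeds
  means <- vapply(1:20, function(sd) {
    genes <- rownames(sim$matrix)[((sd * 37) %% 990) + 1:10]
    mean(module_score(sim$matrix, genes, seed = sd))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("module score drops missing genes with a warning, errors when none left", {
  m <- matrix(runif(100 * 10), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:10)))
  expect_warning(s <- module_score(m, c("g001", "nope"), seed = 1), "absent")
  expect_length(s, 10L)
  expect_error(suppressWarnings(module_score(m, "nope", seed = 1)),
               class = "tcrdrive_parameter_error")
  expect_error(module_score(m[1:10, ], "g001",
                            pipeline_config(score_bins = 24L)),
               class = "tcrdrive_parameter_error")
})

test_that("geometric-mean score matches closed forms and its invariances", {
  m <- matrix(4, nrow = 5, ncol = 3,
              dimnames = list(packaged_gene_sets()$cytotoxicity,
                              c("s1", "s2", "s3")))
  expect_equal(unname(geometric_mean_score(m, rownames(m))), rep(4, 3))

  m2 <- matrix(c(0, 3), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(geometric_mean_score(m2, c("a", "b"), pseudocount = 1)),
               sqrt(1 * 4) - 1)
  m3 <- matrix(c(1, 4), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(geometric_mean_score(m3, c("a", "b"), pseudocount = 0)),
               2.0)
  # permutation invariance in genes; monotone in each gene
  expect_equal(geometric_mean_score(m3, c("b", "a"), 0),
               geometric_mean_score(m3, c("a", "b"), 0))
  m4 <- m3; m4["a", ] <- 2
  expect_gt(geometric_mean_score(m4, c("a", "b"), 0),
            geometric_mean_score(m3, c("a", "b"), 0))
  # missing genes are an error, not a silent drop
  expect_error(geometric_mean_score(m3, c("a", "zzz")),
               class = "tcrdrive_key_error")
})

test_that("packaged gene sets carry the exact published lists", {
  sets <- packaged_gene_sets()
  expect_equal(sets$cytotoxicity, c("GZMA", "GZMH", "GZMM", "PRF1", "GNLY"))
  expect_length(sets$hla_ii, 14L)
  expect_true(all(grepl("^HLA-D", sets$hla_ii)))
  expect_length(sets$scavenger, 27L)
  expect_true(all(c("CD14", "MARCO", "SSC4D", "SSC5D") %in% sets$scavenger))
  expect_false(any(duplicated(unlist(sets))))
})

test_that("gene sets read from GMT and TSV", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG2\tG4"), gmt)
  sets <- read_gene_sets(gmt)
  expect_equal(sets$setA, c("G1", "G2", "G3"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("setA\tG1", "setA\tG2", "setB\tG9"), tsv)
  sets2 <- read_gene_sets(tsv)
  expect_equal(sets2$setB, "G9")
})

test_that("the DE t-test matches an independent Welch oracle per gene", {
  set.seed(13)
  n1 <- 3L; n2 <- 3L
  m <- matrix(abs(rnorm(5 * (n1 + n2), mean = 3)), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:6)))
  labels <- rep(c("grp1", "grp2"), c(n1, n2))
  res <- de_ttest(m, labels)
  for (g in rownames(m)) {
    x <- m[g, labels == "grp1"]; y <- m[g, labels == "grp2"]
    expect_equal(res$p[res$gene == g], welch_oracle(x, y), tolerance = 1e-10)
    expect_equal(res$log2_fc[res$gene == g],
                 (mean(x) - mean(y)) * log2(exp(1)), tolerance = 1e-12)
  }
  # identical values in both groups: untestable (zero variance) -> NA p
  m2 <- rbind(m, const = 2)
  res2 <- de_ttest(m2, labels)
  expect_true(is.na(res2$p[res2$gene == "const"]))
})

test_that("p-value adjustment follows Bonferroni and BH conventions", {
  # Bonferroni multiplies by the number of tested genes, capped at 1
  set.seed(17)
  m <- matrix(abs(rnorm(100 * 8, mean = 3)), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%d", 1:8)))
  labels <- rep(c("a", "b"), each = 4)
  bon <- de_ttest(m, labels, adjust = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, bon$p * 100), tolerance = 1e-12)
  expect_true(all(bon$p_adjusted >= bon$p, na.rm = TRUE))
  bh <- de_ttest(m, labels, adjust = "bh")
  expect_equal(bh$p_adjusted[!is.na(bh$p)],
               p.adjust(bh$p[!is.na(bh$p)], "BH"), tolerance = 1e-12)
  # BH preserves p ordering
  expect_false(is.unsorted(bh$p_adjusted[order(bh$p)]))
  # rank-test companion runs
  wil <- de_test(m, labels, adjust = "bh", test = "wilcox")
  expect_true(all(wil$p_adjusted <= 1, na.rm = TRUE))
})

test_that("planted DE genes reach Bonferroni significance at delta = 2", {
  sim <- generate_expression_matrix(n_genes = 300, n_cells = 400,
                                    planted_idx = 1:5, delta = 2,
                                    subset_fraction = 0.5, seed = 19)
  labels <- ifelse(sim$labels, "marked", "rest")
  res <- de_ttest(sim$matrix, labels)
  hit <- res[res$gene %in% sim$planted_genes, ]
  expect_true(all(hit$p_adjusted < 0.05))
  expect_true(all(hit$log2_fc > 0))
})

test_that("expression matrices round-trip through MTX and dense TSV", {
  sim <- generate_expression_matrix(n_genes = 30, n_cells = 10, seed = 23)
  m <- round(sim$matrix, 4)
  # dense TSV
  dense <- tempfile(fileext = ".tsv")
  write.table(m, dense, sep = "\t", quote = FALSE, col.names = NA)
  back <- read_expression_matrix(dense)
  expect_equal(back, m)
  # MTX triplet
  mtx <- tempfile(fileext = ".mtx")
  genes <- tempfile(); cells <- tempfile()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  writeLines(rownames(m), genes)
  writeLines(colnames(m), cells)
  back2 <- read_expression_matrix(mtx, genes_path = genes, cells_path = cells)
  expect_equal(back2, m, ignore_attr = TRUE)
})
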