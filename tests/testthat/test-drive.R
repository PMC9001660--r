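test_that("leukemic clone identification applies the strict >5% rule", {
  rep <- make_rep(c(7L, 5L, 88L))  # freqs 0.07, 0.05, 0.88 of 100
  cfg <- pipeline_config()
  leuk <- identify_leukemic_clones(rep, cfg)
  freqs <- rep$clonotypes$frequency[match(leuk, rep$clonotypes$key)]
  expect_true(all(freqs > 0.05))
  # boundary: exactly 5% is NOT leukemic
  expect_false(rep$clonotypes$key[rep$clonotypes$frequency == 0.05] %in% leuk)
  # largest first
  expect_equal(freqs, sort(freqs, decreasing = TRUE))

  multi <- make_rep(c(40L, 12L, 3L, rep(1L, 45)))
  expect_length(identify_leukemic_clones(multi, cfg), 2L)
})

test_that("annotation path returns curated keys verbatim and validates them", {
  rep <- make_rep(c(10L, 5L, 85L))
  ann <- rep$clonotypes$key[3]
  expect_equal(identify_leukemic_clones(rep, annotation = ann), ann)
  expect_error(identify_leukemic_clones(rep, annotation = "CNOPEF"),
               class = "tcrdrive_key_error")
})

test_that("drive classification recovers a planted motif group", {
  cfg <- pipeline_config(subsample_depth = 5000L)
  leuk_cdr3 <- "CASSLQRSTNEKLFF"
  partners <- sprintf("CASS%sQRSTGELFF", c("A", "G", "L", "P"))
  others <- bg_cdr3s(60, seed = 301)
  rep <- make_rep(c(3000L, rep(50L, 4), rep(40L, 60)),
                  cdr3 = c(leuk_cdr3, partners, others))
  leuk <- identify_leukemic_clones(rep, cfg)
  expect_equal(leuk, leuk_cdr3)
  dc <- classify_drive(rep, ref_small(), leuk, cfg, seed = 5)
  expect_true(dc$calls$driven)
  # all four planted partners sit in the supporting group (chance members
  # recruited by enriched sub-k-mers of the planted motif may join too)
  gid <- dc$groups$nodes$group_id[dc$groups$nodes$key == leuk_cdr3]
  group_keys <- dc$groups$nodes$key[dc$groups$nodes$group_id == gid]
  expect_true(all(partners %in% group_keys))
  expect_gte(dc$calls$n_nonleukemic_partners, 4L)

  # counterfactual: deleting every planted partner flips the call
  rep2 <- exclude_clonotypes(rep, partners)
  dc2 <- classify_drive(rep2, ref_small(), leuk, cfg, seed = 5)
  expect_false(dc2$calls$driven)

  # a leukemic clone alone in its group is not driven
  expect_true(dc2$calls$n_nonleukemic_partners == 0 || !dc2$calls$driven)

  # empty leukemic set gives an empty call table
  dc3 <- classify_drive(rep, ref_small(), character(), cfg, seed = 5)
  expect_equal(nrow(dc3$calls), 0L)
})

test_that("exclude-leukemic mode classifies re-inserted query clones", {
  cfg <- pipeline_config(subsample_depth = 2000L)
  leuk_cdr3 <- "CASSLQRSTNEKLFF"
  partners <- sprintf("CASS%sQRSTGELFF", c("A", "G", "L", "P"))
  others <- bg_cdr3s(60, seed = 302)
  rep <- make_rep(c(3000L, rep(50L, 4), rep(40L, 60)),
                  cdr3 = c(leuk_cdr3, partners, others))
  dc <- classify_drive(rep, ref_small(), leuk_cdr3, cfg,
                       mode = "exclude_leukemic", seed = 5)
  expect_true(dc$calls$driven)
  expect_equal(dc$calls$mode, "exclude_leukemic")
  # the leukemic clone is a query node: not part of the subsampled reads
  expect_false(leuk_cdr3 %in% dc$repertoire$clonotypes$key)
  expect_true(leuk_cdr3 %in% dc$groups$nodes$key)
})

test_that("drive calls are reproducible and stable across seeds on a strong fixture", {
  cfg <- pipeline_config(subsample_depth = 2000L)
  leuk_cdr3 <- "CASSLQRSTNEKLFF"
  partners <- sprintf("CASS%sQRSTGELFF", c("A", "G", "L", "P"))
  others <- bg_cdr3s(60, seed = 303)
  # partners at 1% each of 5000 reads
  rep <- make_rep(c(1000L, rep(50L, 4), rep(47L, 60)),
                  cdr3 = c(leuk_cdr3, partners, others))
  a <- classify_drive(rep, ref_small(), leuk_cdr3, cfg, seed = 17)
  b <- classify_drive(rep, ref_small(), leuk_cdr3, cfg, seed = 17)
  expect_identical(a$calls, b$calls)
  calls <- vapply(1:50, function(s)
    classify_drive(rep, ref_small(), leuk_cdr3, cfg, seed = s)$calls$driven,
    logical(1))
  expect_gte(mean(calls, na.rm = TRUE), 0.95)
})

test_that("cohort drive prevalence uses the one-sided Fisher test", {
  tab <- data.frame(cohort = c("T-LGLL", "healthy"),
                    n_samples = c(6L, 6L), n_driven = c(6L, 0L))
  out <- compare_drive_prevalence(tab)
  expect_equal(out$p_vs_focal[2], 1 / choose(12, 6), tolerance = 1e-12)
  expect_true(is.na(out$p_vs_focal[1]))

  # identical proportions: no evidence of enrichment
  same <- compare_drive_prevalence(
    data.frame(cohort = c("a", "b"), n_samples = c(10L, 10L),
               n_driven = c(5L, 5L)))
  expect_gte(same$p_vs_focal[2], 0.5)

  # printed cohort sizes: 12/17 MNC-sorted vs 3/29 melanoma-style
  obs <- compare_drive_prevalence(
    data.frame(cohort = c("T-LGLL", "SKCM"), n_samples = c(17L, 29L),
               n_driven = c(12L, 3L)))
  expect_equal(obs$p_vs_focal[2], fisher_oracle(12, 17, 3, 29),
               tolerance = 1e-10)
  expect_lt(obs$p_vs_focal[2], 0.05)

  expect_error(compare_drive_prevalence(
    data.frame(cohort = "a", n_samples = 3L, n_driven = 1L)),
    class = "tcrdrive_parameter_error")
  expect_error(compare_drive_prevalence(
    data.frame(cohort = c("a", "b"), n_samples = c(0L, 3L),
               n_driven = c(0L, 1L))),
    class = "tcrdrive_parameter_error")
})

test_that("prevalence p-values match exact enumeration on all small tables", {
  for (n1 in c(4L, 7L)) {
    for (n2 in c(5L, 9L)) {
      for (k1 in 0:n1) {
        for (k2 in 0:n2) {
          out <- compare_drive_prevalence(
            data.frame(cohort = c("x", "y"), n_samples = c(n1, n2),
                       n_driven = c(k1, k2)))
          expect_equal(out$p_vs_focal[2], fisher_oracle(k1, n1, k2, n2),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("clone-size comparison reproduces exact Mann-Whitney results", {
  res <- compare_clone_sizes_by_drive(
    c(0.3, 0.4, 0.5, 0.01, 0.02, 0.03),
    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$statistic, 9)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$median_driven, 0.4)
  expect_equal(res$median_not_driven, 0.02)

  # identical samples in both groups: p = 1
  same <- compare_clone_sizes_by_drive(
    rep(c(0.1, 0.2, 0.3), 2), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$p_value, 1)

  expect_error(compare_clone_sizes_by_drive(c(0.1), c(TRUE)),
               class = "tcrdrive_parameter_error")
})

test_that("tied observations use mid-ranks and match the exhaustive oracle", {
  set.seed(23)
  for (i in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    # coarse grid forces cross-group ties
    x <- sample(seq(0.1, 0.5, by = 0.1), n1, replace = TRUE)
    y <- sample(seq(0.1, 0.5, by = 0.1), n2, replace = TRUE)
    got <- compare_clone_sizes_by_drive(c(x, y),
                                        rep(c(TRUE, FALSE), c(n1, n2)))
    expect_equal(got$p_value, mw_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("large groups fall back to the tie-corrected normal approximation", {
  set.seed(29)
  x <- rexp(30); y <- rexp(35) * 1.5
  got <- compare_clone_sizes_by_drive(c(x, y), rep(c(TRUE, FALSE), c(30, 35)))
  want <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  expect_equal(got$method, "normal")
})
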