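test_that("local motif extraction trims the CDR3 and enumerates k-mers", {
  m <- extract_local_motifs("CASSIRSSYEQYF")
  # core SIRSSYEQ -> 6 3-mers + 5 4-mers
  expect_length(m, 11L)
  expect_setequal(m[nchar(m) == 3],
                  c("SIR", "IRS", "RSS", "SSY", "SYE", "YEQ"))
  expect_setequal(m[nchar(m) == 4],
                  c("SIRS", "IRSS", "RSSY", "SSYE", "SYEQ"))

  cfg3 <- pipeline_config(motif_lengths = 3L)
  expect_setequal(extract_local_motifs("CASSAAAYF", cfg3), c("SAA", "AAA"))
  # length-7 CDR3: core "SQ" is shorter than k -> empty set, not an error
  expect_length(extract_local_motifs("CASSQYF", cfg3), 0L)
  expect_error(extract_local_motifs("CASS1F"), class = "tcrdrive_validation_error")
})

test_that("motif enrichment p-values match the brute-force hypergeometric oracle", {
  # all 2x2 tables with small margins
  for (A in c(3, 7, 12)) {
    for (B in c(5, 11, 18)) {
      for (a in 0:A) {
        for (b in 0:B) {
          expect_equal(tcrdrive:::fisher_greater_p(a, A, b, B),
                       fisher_oracle(a, A, b, B), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("motif enrichment applies the support floor, fold rule and smoothing", {
  cfg <- pipeline_config(motif_lengths = 4L)
  # planted motif QRST in 5 sample CDR3s; reference has it nowhere
  sample_cdr3 <- c(sprintf("CASS%sQRSTYEQYF", c("A", "G", "L", "P", "V")),
                   sprintf("CASSN%sWGAGYEQYF", aa_tag(1:40)))
  ref <- ref_small()
  rec <- motif_enrichment(sample_cdr3, ref, cfg)
  qr <- rec[rec$motif == "QRST", ]
  expect_equal(qr$n_sample, 5L)
  expect_true(qr$enriched)
  # Haldane-style smoothed fold when n_ref = 0
  if (qr$n_ref == 0) {
    expect_equal(qr$fold, (5 / qr$n_sample_total) / (0.5 / qr$n_ref_total))
  }
  # motif in a single CDR3 is never tested
  single <- rec[rec$n_sample < 2, ]
  expect_equal(nrow(single), 0L)
  # a motif with matching sample and reference rates is not enriched
  expect_false(any(rec$enriched & rec$fold < cfg$min_fold))
  # reference guard
  expect_error(motif_enrichment(sample_cdr3, c("CASSLF", "CASSYF"), cfg),
               class = "tcrdrive_parameter_error")
})

test_that("enrichment fold and p come from the stated 2x2 table", {
  # 5/100 sample vs 10/10000 reference: fold 50, p = hypergeometric tail
  p <- tcrdrive:::fisher_greater_p(5, 100, 10, 10000)
  expect_equal(p, fisher_oracle(5, 100, 10, 10000), tolerance = 1e-12)
  fold <- (5 / 100) / (10 / 10000)
  expect_equal(fold, 50)
})

test_that("global pairs equal the O(n^2) brute force on random CDR3s", {
  set.seed(7)
  aa <- c("A", "G", "S", "L", "Y", "E", "Q", "T")
  cdr3 <- vapply(1:200, function(i) {
    L <- sample(10:14, 1)
    paste0("C", paste(sample(aa, L - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
  # plant a near-identical pair and an identical pair to guarantee edges
  cdr3[1] <- "CASSLGETQYF"; cdr3[2] <- "CASSLGDTQYF"; cdr3[3] <- "CASSLGETQYF"
  got <- global_pairs(cdr3)
  want <- global_pairs_oracle(cdr3)
  expect_equal(got[order(got$i, got$j), ], want[order(want$i, want$j), ],
               ignore_attr = TRUE)
  expect_true(any(got$i == 1 & got$j == 2 & got$distance == 1))
  expect_true(any(got$i == 1 & got$j == 3 & got$distance == 0))
  # different lengths never linked
  expect_false(any(nchar(cdr3[got$i]) != nchar(cdr3[got$j])))
  expect_equal(nrow(global_pairs(character())), 0L)
})

test_that("planted-motif groups are recovered as one significant component", {
  cfg <- pipeline_config(subsample_depth = 1000L)
  members <- sprintf("CASS%sQRSTGELFF", c("A", "G", "L"))
  others <- sprintf("CASSN%sWGAGYNEKLFF", aa_tag(1:30))
  rep <- make_rep(rep(5L, 33), cdr3 = c(members, others))
  gr <- build_specificity_groups(rep, ref_small(), cfg)
  gid <- unique(gr$nodes$group_id[gr$nodes$cdr3_aa %in% members])
  expect_length(gid, 1L)
  grp <- gr$groups[gr$groups$group_id == gid, ]
  expect_true(grp$significant)
  expect_equal(grp$n_members, 3L)
  expect_true("QRST" %in% strsplit(grp$motifs, ";")[[1]])
})

test_that("dissimilar repertoires give only non-significant singleton groups", {
  # mutually dissimilar = pairwise-disjoint motif sets, selected greedily
  pool <- generate_reference_repertoire(400, seed = 5)$clonotypes$cdr3_aa
  cfg0 <- pipeline_config()
  seen <- character()
  cdr3 <- character()
  for (s in pool) {
    mm <- unique(extract_local_motifs(s, cfg0))
    if (length(mm) && !any(mm %in% seen)) {
      cdr3 <- c(cdr3, s)
      seen <- c(seen, mm)
      if (length(cdr3) == 25L) break
    }
  }
  rep <- make_rep(rep(2L, 25), cdr3 = cdr3)
  gr <- build_specificity_groups(rep, ref_small(), pipeline_config())
  multi <- gr$groups[gr$groups$n_members >= 2 & gr$groups$significant, ]
  expect_equal(nrow(multi), 0L)
})

test_that("a global edge whose pattern matches reference rates is not significant", {
  # two clones one substitution apart; the same near-pattern planted densely
  # in the reference so the pattern is not enriched
  a <- "CASSLGETQYF"; b <- "CASSLGDTQYF"
  ref_cdr3 <- c(sprintf("CASSLG%sTQYF", c("A", "C", "D", "E", "F", "G", "H",
                                          "I", "K", "L", "M", "N", "P", "Q",
                                          "R", "S", "T", "V", "W", "Y")),
                generate_reference_repertoire(180, seed = 9)$clonotypes$cdr3_aa)
  rep <- make_rep(rep(3L, 12),
                  cdr3 = c(a, b, sprintf("CAWW%sGNIPAYNF", aa_tag(1:10))))
  gr <- build_specificity_groups(rep, ref_cdr3, pipeline_config())
  gid <- gr$nodes$group_id[gr$nodes$cdr3_aa == a]
  expect_equal(gr$nodes$group_id[gr$nodes$cdr3_aa == b], gid)
  grp <- gr$groups[gr$groups$group_id == gid, ]
  expect_equal(grp$n_global_edges, 1L)
  expect_false(grp$significant)
})

test_that("component membership is invariant to input order", {
  cfg <- pipeline_config()
  members <- sprintf("CASS%sQRSTGELFF", c("A", "G", "L"))
  others <- sprintf("CASSN%sWGAGYNEKLFF", aa_tag(1:15))
  cdr3 <- c(members, others)
  rep1 <- make_rep(rep(4L, length(cdr3)), cdr3 = cdr3)
  set.seed(13)
  perm <- sample(length(cdr3))
  rep2 <- make_rep(rep(4L, length(cdr3))[perm], cdr3 = cdr3[perm])
  g1 <- build_specificity_groups(rep1, ref_small(), cfg)
  g2 <- build_specificity_groups(rep2, ref_small(), cfg)
  # same partition: compare member strings of groups
  expect_setequal(g1$groups$members, g2$groups$members)
  expect_equal(g1$groups$significant[order(g1$groups$members)],
               g2$groups$significant[order(g2$groups$members)])
})

test_that("GraphML export writes node and edge attributes", {
  members <- sprintf("CASS%sQRSTGELFF", c("A", "G"))
  rep <- make_rep(c(5L, 3L, 2L),
                  cdr3 = c(members, "CASSNWGAGYNEKLFF"))
  rep$clonotypes$leukemic <- c(TRUE, FALSE, FALSE)
  gr <- build_specificity_groups(rep, ref_small(), pipeline_config())
  path <- tempfile(fileext = ".graphml")
  write_groups_graphml(gr, path)
  txt <- readLines(path)
  expect_true(any(grepl("frequency", txt)))
  expect_true(any(grepl("evidence", txt)))
})
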