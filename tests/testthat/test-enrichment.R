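test_that("the running sum walks the hand-enumerated path", {
  r <- make_ranked(paste0("g", 1:5), c(3, 2, 1, -1, -2))
  res <- enrichment_score(r, "g1", p = 1)
  expect_equal(res$running_sum, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(res$es, 1)
  expect_identical(res$leading_edge, "g1")
  # a set parked at the bottom scores negative
  expect_lt(enrichment_score(r, c("g4", "g5"), p = 1)$es, 0)
  # degenerate sets are rejected
  expect_error(enrichment_score(r, "absent"), "no member")
  expect_error(enrichment_score(r, paste0("g", 1:5)), "entire universe")
})

test_that("ES is bounded and, at p = 0, invariant to monotone rescaling", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(10:80, 1)
    r <- make_ranked(sprintf("g%03d", 1:n), rnorm(n))
    set <- sample(r$gene, sample(2:min(8, n - 1), 1))
    for (p in c(0, 1, 2)) {
      es <- enrichment_score(r, set, p)$es
      expect_gte(es, -1); expect_lte(es, 1)
    }
    # strictly monotone metric rescaling preserves order, hence p=0 ES
    r2 <- r; r2$metric <- exp(r2$metric / 3) + 5
    expect_equal(enrichment_score(r2, set, 0)$es,
                 enrichment_score(r, set, 0)$es)
  }
})

test_that("the weighted statistic agrees with an independent implementation", {
  library(fgsea)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(40:150, 1)
    r <- make_ranked(sprintf("g%03d", 1:n), rnorm(n))
    set <- sample(r$gene, sample(3:12, 1))
    ours <- enrichment_score(r, set, p = 1)$es
    ref <- fgsea::calcGseaStat(setNames(r$metric, r$gene),
                               selectedStats = which(r$gene %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("the hit-position shortcut equals the full running sum", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(15:90, 1); k <- sample(2:10, 1)
    r <- make_ranked(sprintf("g%03d", 1:n), rnorm(n))
    pos <- sort(sample(n, k))
    a <- enrichment_score(r, r$gene[pos], p = 1)$es
    b <- ptisig:::.es_from_positions(pos, abs(r$metric), n)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("permutation GSEA is deterministic and separates planted sets", {
  set.seed(4)
  genes <- sprintf("g%04d", 1:800)
  r <- make_ranked(genes, sort(rnorm(800), decreasing = TRUE))
  planted <- sample(genes[1:60], 25)
  rando <- sample(genes, 25)
  res <- gsea_preranked(r, list(planted = planted, rando = rando),
                        n_perm = 500, seed = 5)
  res2 <- gsea_preranked(r, list(planted = planted, rando = rando),
                         n_perm = 500, seed = 5)
  expect_identical(res$nes, res2$nes)
  expect_identical(res$fdr_q, res2$fdr_q)
  expect_gt(res$nes[res$set == "planted"], res$nes[res$set == "rando"])
  expect_lte(res$fdr_q[res$set == "planted"], 0.25)
  # sign(nes) matches sign(es); q-values live in [0, 1]
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  # zero-overlap sets are flagged, not scored
  res3 <- gsea_preranked(r, list(ghost = c("zz1", "zz2"), planted = planted),
                         n_perm = 100, seed = 5)
  expect_equal(res3$size[res3$set == "ghost"], 0)
  expect_true(is.na(res3$es[res3$set == "ghost"]))
  expect_false(is.na(res3$fdr_q[res3$set == "planted"]))
})

test_that("average-CPM scores are per-sample set means", {
  cpm <- cbind(s1 = c(10, 30, 100), s2 = c(20, 40, 100))
  rownames(cpm) <- c("g1", "g2", "g3")
  ne <- make_ne(cpm, c(s1 = "P", s2 = "PTR"))
  sc <- average_cpm_score(ne, c("g1", "g2"))
  expect_equal(unname(sc), c(20, 30), ignore_attr = TRUE)
  # singleton set returns the gene's own cpm row
  expect_equal(unname(average_cpm_score(ne, "g3")), c(100, 100),
               ignore_attr = TRUE)
  # permuting samples permutes scores identically
  ne_rev <- make_ne(cpm[, 2:1], c(s1 = "P", s2 = "PTR"))
  expect_equal(average_cpm_score(ne_rev, c("g1", "g2")),
               sc[c("s2", "s1")], ignore_attr = TRUE)
  # absent genes are reported; full miss errors
  sc2 <- average_cpm_score(ne, c("g1", "nope"))
  expect_identical(attr(sc2, "missing_genes"), "nope")
  expect_error(average_cpm_score(ne, "nope"), "no signature gene")
})

test_that("score comparisons follow Welch-test conventions", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  cmp <- compare_scores(a, b)
  expect_equal(cmp$difference, -10)
  expect_lt(cmp$p_value, 0.01)
  # identical groups: zero difference, p = 1
  same <- compare_scores(a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  # swapping groups flips the sign, not the p-value
  rev <- compare_scores(b, a)
  expect_equal(rev$difference, 10)
  expect_equal(rev$p_value, cmp$p_value)
  # both sides constant and equal: p = 1 by convention
  expect_equal(compare_scores(c(2, 2), c(2, 2))$p_value, 1)
  # one sample per side: only the difference
  one <- compare_scores(5, 3)
  expect_equal(one$difference, 2)
  expect_true(is.na(one$p_value))
})

test_that("GMT files round-trip gene sets", {
  f <- tempfile(fileext = ".gmt")
  sets <- list(alpha = c("a", "b", "c"), beta = c("d", "e"))
  write_gmt(sets, f, description = "test sets")
  expect_identical(read_gmt(f), sets)
  writeLines("broken\tonly-two-fields", f)
  expect_error(read_gmt(f), "malformed")
})
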