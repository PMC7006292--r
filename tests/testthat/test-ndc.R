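test_that("ndc_score implements the normalized difference arithmetic", {
  expect_equal(ndc_score(0.8, 0.1, 0.3), 4.9)
  expect_equal(ndc_score(0.5, -0.5, 0.25), 0)
  expect_equal(ndc_score(0.9, 0, 0.2, eps = 1e-8), 7e7)
  # vectorised and sign-preserving
  expect_equal(ndc_score(c(0.8, 0.5), c(0.1, -0.5), 0.3),
               c(4.9, (0.5 - 0.25 - 0.3) / 0.5))
})

test_that("the permutation threshold is the nearest-rank fractile", {
  sim <- simulate_expression(15, pattern_spec("null", 30), seed = 5)
  null <- perm_threshold(sim$mat, sim$labels, n_perm = 200, level = 0.95,
                         seed = 5)
  expect_equal(length(null$values), 200L)
  expect_false(is.unsorted(null$values))
  expect_identical(null$threshold, null$values[ceiling(0.95 * 200)])
  expect_gte(null$threshold, 0)
  expect_lte(null$threshold, 1)

  # other fractile levels obey the same nearest-rank rule
  null80 <- perm_threshold(sim$mat, sim$labels, n_perm = 150, level = 0.8,
                           seed = 5)
  expect_identical(null80$threshold, null80$values[ceiling(0.8 * 150)])

  expect_error(perm_threshold(sim$mat, sim$labels, n_perm = 50), "100")
  allconst <- matrix(1, 5, 30, dimnames = list(paste0("g", 1:5), colnames(sim$mat)))
  expect_error(perm_threshold(allconst, sim$labels), "constant")
})

test_that("permutation runs are reproducible and seed-sensitive", {
  sim <- simulate_expression(12, pattern_spec("null", 20), seed = 3)
  a <- perm_threshold(sim$mat, sim$labels, n_perm = 120, seed = 7)
  b <- perm_threshold(sim$mat, sim$labels, n_perm = 120, seed = 7)
  c <- perm_threshold(sim$mat, sim$labels, n_perm = 120, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("score_all handles perfect, constant, and label-identical genes", {
  labels <- rep(0:1, each = 6)
  mat <- rbind(perfect = c(1:6, 101:106),
               flatline = rep(4, 12),
               labelcopy = as.numeric(labels))
  colnames(mat) <- paste0("s", 1:12)
  expect_warning(sc <- score_all(mat, labels, null = 0.2), "sentinel")
  expect_equal(sc$gene_id, rownames(mat))  # input order preserved
  expect_equal(sc$mic[1], 1)
  expect_identical(sc$ndc[2], -Inf)
  expect_true(is.na(sc$r[2]))
  expect_equal(sc$r[3], 1)
  expect_equal(sc$ndc[3], (1 - 1 - 0.2) / 1)

  # permuting gene order permutes the output identically
  expect_warning(sc2 <- score_all(mat[c(3, 1, 2), ], labels, null = 0.2))
  expect_equal(sc2[order(sc2$gene_id), ], sc[order(sc$gene_id), ],
               ignore_attr = TRUE)

  # positive rescaling of expression changes neither mic nor r
  sc3 <- score_all(mat["perfect", , drop = FALSE] * 3.5, labels, null = 0.2)
  expect_equal(sc3$mic, sc$mic[1])
  expect_equal(sc3$r, sc$r[1])
})

test_that("the two-stage ranking re-sorts only the top pool by MIC", {
  scores <- data.frame(gene_id = c("A", "B", "C", "D", "E"),
                       ndc = c(5, 4, 3, 2, 1),
                       mic = c(0.4, 0.9, 0.6, 0.95, 0.1))
  expect_equal(final_ranking(scores, top_pool = 3), c("B", "C", "A", "D", "E"))
  expect_equal(final_ranking(scores, top_pool = 5), c("D", "B", "C", "A", "E"))
  expect_equal(final_ranking(scores, top_pool = 1), c("A", "B", "C", "D", "E"))
  # deterministic tie-breaks: ndc ties fall back to mic then id in stage 1
  tied <- data.frame(gene_id = c("b", "a", "c"), ndc = c(1, 1, 1),
                     mic = c(0.5, 0.5, 0.7))
  expect_equal(final_ranking(tied, top_pool = 1), c("c", "a", "b"))
  expect_error(final_ranking(scores[0, ], 10), "non-empty")
})

test_that("the full pipeline is reproducible and internally consistent", {
  sim <- simulate_expression(15, list(pattern_spec("null", 25),
                                      pattern_spec("bimodal", 3),
                                      pattern_spec("linear_de", 4)), seed = 9)
  r1 <- ndc_rank(sim$mat, sim$labels, n_perm = 150, seed = 9, top_pool = 10)
  r2 <- ndc_rank(sim$mat, sim$labels, n_perm = 150, seed = 9, top_pool = 10)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$null$threshold, r2$null$threshold)

  sc <- r1$scores
  # rank_ndc is a permutation; rank_final covers exactly the pool
  expect_setequal(sc$rank_ndc, seq_len(nrow(sc)))
  expect_equal(sum(!is.na(sc$rank_final)), 10L)
  # Eq-style identity holds row by row for non-degenerate genes
  ok <- is.finite(sc$ndc)
  expect_equal(sc$ndc[ok],
               (sc$mic[ok] - sc$r2[ok] - r1$null$threshold) /
                 pmax(abs(sc$r[ok]), 1e-8))
  # the rank_final order matches final_ranking applied to the scores
  fin <- final_ranking(sc, top_pool = 10)
  expect_equal(sc$gene_id[order(sc$rank_final)][1:10], fin[1:10])
})
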