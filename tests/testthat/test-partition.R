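test_that("cohesive clusters match hand-computed cohesiveness", {
  tri <- data.frame(tf_a = c("a", "a", "b"), tf_b = c("b", "c", "c"),
                    weight = 1)
  cs <- cluster_one(tri, penalty = 0, min_size = 3, min_density = 0)
  expect_equal(max(cs$cohesiveness), 1.0)
  expect_true(any(vapply(cs$clusters, function(cl)
    setequal(cl, c("a", "b", "c")), logical(1))))
  # two unit triangles joined by a weak bridge: each triangle has
  # f = 3 / (3 + 0.1) (the full graph is also emitted at p = 0, where
  # a boundary-free superset maximises the objective)
  g2 <- data.frame(tf_a = c("a", "a", "b", "d", "d", "e", "c"),
                   tf_b = c("b", "c", "c", "e", "f", "f", "d"),
                   weight = c(1, 1, 1, 1, 1, 1, 0.1))
  cs2 <- cluster_one(g2, penalty = 0, min_size = 3, min_density = 0)
  tri_f <- cs2$cohesiveness[vapply(cs2$clusters, function(cl)
    setequal(cl, c("a", "b", "c")) || setequal(cl, c("d", "e", "f")),
    logical(1))]
  expect_length(tri_f, 2)
  expect_equal(tri_f, rep(3 / 3.1, 2), tolerance = 1e-12)
  # empty graph
  empty <- cluster_one(data.frame(tf_a = character(0),
                                  tf_b = character(0)))
  expect_length(empty$clusters, 0)
})

test_that("stored cohesiveness is recomputable from the graph", {
  for (e in fixture_graphs()[1:4]) {
    cs <- cluster_one(e, penalty = 1, min_size = 1, min_density = 0)
    A <- tfnetdev:::.edge_adjacency(e)
    for (i in seq_along(cs$clusters))
      expect_equal(cs$cohesiveness[i],
                   tfnetdev:::.cohesiveness(A, cs$clusters[[i]], 1),
                   tolerance = 1e-12)
  }
})

test_that("greedy clusters approach the exhaustive optimum", {
  for (e in fixture_graphs()[1:5]) {
    for (pen in c(0.5, 2)) {
      cs <- cluster_one(e, penalty = pen, min_size = 1, min_density = 0,
                        overlap_threshold = 1)
      expect_gte(max(cs$cohesiveness),
                 0.9 * cohesiveness_optimum(e, pen))
    }
  }
})

test_that("overlap merging is idempotent", {
  sets <- list(c("a", "b", "c", "d"), c("a", "b", "c", "e"), c("x", "y", "z"))
  m1 <- tfnetdev:::.merge_overlapping(sets, 0.5)
  m2 <- tfnetdev:::.merge_overlapping(m1, 0.5)
  expect_identical(m1, m2)
})

test_that("hypergeometric enrichment equals the enumeration oracle", {
  universe <- sprintf("u%04d", 1:1000)
  ann <- list(t1 = universe[1:10])
  e <- hypergeometric_enrichment(universe[1:10], ann, universe)
  expect_equal(e$p, 1 / choose(1000, 10), tolerance = 1e-12)
  expect_lt(e$padj, 1e-20)
  # disjoint term
  e2 <- hypergeometric_enrichment(universe[1:10],
                                  list(t1 = universe[900:950]), universe)
  expect_gte(e2$p, 0.99)
  # oracle over a parameter grid
  set.seed(19)
  for (N in c(20, 35, 50)) {
    uni <- sprintf("x%02d", seq_len(N))
    for (m in c(3, 7, 12)) {
      for (csz in c(4, 9)) {
        ann <- list(term = uni[seq_len(m)])
        cl <- uni[sample.int(N, csz)]
        got <- hypergeometric_enrichment(cl, ann, uni)
        k <- length(intersect(cl, ann$term))
        expect_equal(got$p, hyper_upper_oracle(k, m, N - m, csz),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("two-tailed pathway overlap doubles a capped upper tail", {
  po <- pathway_overlap_test(paste0("x", 1:5), paste0("x", 1:4),
                             paste0("x", 1:10))
  expect_equal(po$p_upper, 5 / 210, tolerance = 1e-12)
  expect_equal(po$p_two_tailed, 10 / 210, tolerance = 1e-12)
  # empty overlap
  po0 <- pathway_overlap_test(character(0), paste0("x", 1:3),
                              paste0("x", 1:10))
  expect_equal(po0$p_two_tailed, 1)
  # minimum-possible k forces the cap
  po_cap <- pathway_overlap_test(paste0("x", 1:3), paste0("x", 2:4),
                                 paste0("x", 1:4))
  expect_equal(po_cap$p_two_tailed, 1)
  expect_error(pathway_overlap_test(paste0("x", 1:9), paste0("x", 1:3),
                                    paste0("x", 1:9), pathway_size = 5),
               "smaller")
})

test_that("random-network null is seeded and calibrated on decoys", {
  sim <- default_sim()
  tfs <- default_tfs()
  decoys <- sim$dataset$annotations
  decoys$sets <- decoys$sets[grep("decoy", names(decoys$sets))]
  n1 <- random_network_null(tfs, c(10, 20, 30), decoys, n_draws = 30,
                            seed = 5, universe = tfs)
  n2 <- random_network_null(tfs, c(10, 20, 30), decoys, n_draws = 30,
                            seed = 5, universe = tfs)
  expect_identical(n1$best_padj, n2$best_padj)
  expect_lte(n1$frac_sig, 0.2)
  expect_error(random_network_null(tfs[1:5], 10, decoys), "pool")
})

test_that("planted clusters beat the size-matched null", {
  sim <- default_sim()
  tfs <- default_tfs()
  clusters <- sim$truth$functional_groups
  obs <- vapply(clusters, function(cl)
    min(hypergeometric_enrichment(cl, sim$dataset$annotations,
                                  universe = tfs)$padj), numeric(1))
  nn <- random_network_null(tfs, lengths(clusters),
                            sim$dataset$annotations, n_draws = 30,
                            seed = 6, observed_best_p = obs,
                            universe = tfs)
  expect_gte(nn$observed_frac_sig, 0.8)
  expect_lte(nn$frac_sig, 0.05)
  expect_lt(nn$wilcox_p, 0.01)
})

test_that("degree power-law check finds preferential-attachment scaling", {
  set.seed(18)
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  res <- degree_powerlaw_check(igraph::degree(g))
  expect_lt(res$exponent, 0)
  expect_gte(res$r_squared, 0.7)
  # complete graph: single degree value, undefined fit
  res2 <- degree_powerlaw_check(rep(19, 20))
  expect_true(is.na(res2$exponent))
  # deterministic
  expect_identical(res, degree_powerlaw_check(igraph::degree(g)))
})
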