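test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(n_genes = 150, n_tfs = 30, seed = 7)
  s1 <- simulate_timecourse(cfg)
  s2 <- simulate_timecourse(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_timecourse(sim_config(n_genes = 150, n_tfs = 30,
                                       seed = 8))
  expect_false(identical(s1$dataset$counts$values,
                         s3$dataset$counts$values))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(n_genes = 10, n_tfs = 5, n_modules = 20),
               "modules")
  expect_error(sim_config(replicates_per_timepoint = c(3, 3)), "one entry")
  expect_error(sim_config(replicates_per_timepoint = c(3, 3, 3, 1, 3)),
               ">= 2 replicates")
})

test_that("counts are nonnegative integers and samples match metadata", {
  ds <- default_sim()$dataset
  expect_true(all(ds$counts$values >= 0))
  expect_true(all(ds$counts$values == round(ds$counts$values)))
  expect_setequal(colnames(ds$counts$values), ds$counts$sample_meta$sample)
})

test_that("noise-free limit leaves only Poisson sampling variation", {
  cfg <- sim_config(n_genes = 200, n_tfs = 40, nb_dispersion = 0,
                    noise_sd = 0, regulator_coupling = 0,
                    library_size_mean = 2e7, seed = 3)
  sim <- simulate_timecourse(cfg)
  # depth varies between replicates, so compare on the FPKM scale
  v <- compute_fpkm(sim$dataset$counts)$values
  cnt <- sim$dataset$counts$values
  tp <- sim$dataset$counts$sample_meta$timepoint
  cols <- sim$dataset$counts$sample_meta$sample[tp == levels(tp)[1]]
  m <- rowMeans(cnt[, cols])
  cv <- apply(v[, cols], 1, stats::sd) / rowMeans(v[, cols])
  expect_true(all(cv[m >= 1e4] < 0.05))
})

test_that("per-sample totals track the planted library sizes", {
  cfg <- sim_config(n_genes = 1000, n_tfs = 100, nb_dispersion = 0.001,
                    library_size_mean = 1e6, seed = 11)
  sim <- simulate_timecourse(cfg)
  rel <- abs(colSums(sim$dataset$counts$values) -
               sim$dataset$library_sizes) / sim$dataset$library_sizes
  expect_true(all(rel < 0.01))
})

test_that("planted modules separate within- from between-module profiles", {
  sim <- default_sim()
  lg <- default_log2()
  mod <- sim$truth$module_of_gene
  pc <- stats::cor(t(lg[names(mod)[!is.na(mod)], ]))
  mm <- mod[rownames(pc)]
  same <- outer(mm, mm, "==") & upper.tri(pc)
  diff <- outer(mm, mm, "!=") & upper.tri(pc)
  expect_gt(mean(pc[same]), mean(pc[diff]))
})

test_that("module recovery degrades monotonically with noise", {
  skip_if_not_installed("mclust")
  ari_at <- function(noise) {
    sim <- simulate_timecourse(sim_config(n_genes = 300, n_tfs = 60,
                                          noise_sd = noise, seed = 5))
    lg <- log2(average_replicates(
      compute_fpkm(sim$dataset$counts))$values + 1)
    mod <- sim$truth$module_of_gene
    mg <- names(mod)[!is.na(mod)]
    mg <- mg[apply(lg[mg, ], 1, stats::sd) > 0]  # all-zero at high noise
    tom <- tom_similarity(abs(stats::cor(t(lg[mg, ])))^12)
    ma <- detect_modules(tom, lg[mg, ])
    mclust::adjustedRandIndex(ma$module, mod[mg])
  }
  a <- vapply(c(0.2, 1, 3), ari_at, numeric(1))
  expect_true(a[1] >= a[2] - 0.05 && a[2] >= a[3] - 0.05)
  expect_gt(a[1], a[3])
})

test_that("annotation simulation reproduces and corrupts planted groups", {
  tr <- default_sim()$truth
  tfs <- default_sim()$dataset$tf_ids
  ann0 <- simulate_annotations(tr, n_decoy_terms = 0, decoy_size = 5,
                               mislabel_rate = 0, seed = 2,
                               tf_pool = tfs)
  expect_identical(ann0$sets, tr$functional_groups)
  g20 <- tr$functional_groups[[1]][1:20]
  tr20 <- tr
  tr20$functional_groups <- list(fg = g20)
  ann5 <- simulate_annotations(tr20, n_decoy_terms = 0, decoy_size = 5,
                               mislabel_rate = 0.5, seed = 2,
                               tf_pool = tfs)
  expect_length(ann5$sets$fg, 20)
  expect_equal(sum(!(ann5$sets$fg %in% g20)), 10)
  expect_error(simulate_annotations(tr, 2, length(tfs) + 1, 0, 1,
                                    tf_pool = tfs), "decoy_size")
})

test_that("prior-edge simulation hits the requested recall and precision", {
  tr <- default_sim()$truth
  wg <- tfnetdev:::.within_group_pairs(tr$functional_groups)
  pr_full <- simulate_prior_edges(tr, recall = 1, precision = 1, seed = 4)
  expect_equal(nrow(pr_full), nrow(wg))
  expect_true(all(pr_full$true_prior))
  pr_half <- simulate_prior_edges(tr, recall = 0.5, precision = 0.5,
                                  seed = 4)
  n_true <- sum(pr_half$true_prior)
  expect_equal(n_true, round(0.5 * nrow(wg)))
  expect_equal(sum(!pr_half$true_prior), n_true)
  wg_keys <- tfnetdev:::.pair_key(wg$tf_a, wg$tf_b)
  false_keys <- with(pr_half[!pr_half$true_prior, ],
                     tfnetdev:::.pair_key(tf_a, tf_b))
  expect_false(any(false_keys %in% wg_keys))
})

test_that("conditional knockout plants the expected contrast", {
  sim <- default_sim()
  tr <- sim$truth; ds <- sim$dataset
  master <- unique(tr$regulator_edges$regulator)[1]
  ck <- simulate_cko(tr, ds, master, effect_size = log(4), seed = 9)
  expect_lt(mean(ck$cko[master, ]), 1)
  expect_setequal(ck$de_genes,
                  c(master, tr$regulator_edges$target[
                    tr$regulator_edges$regulator == master]))
  ck0 <- simulate_cko(tr, ds, master, effect_size = 0, seed = 9)
  expect_identical(ck0$de_genes, master)
  leaf <- setdiff(tr$regulator_edges$target, tr$regulator_edges$regulator)[1]
  expect_error(simulate_cko(tr, ds, leaf, log(4)), "no outgoing")
})

test_that("datasets round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_timecourse(sim_config(n_genes = 120, n_tfs = 24,
                                        seed = 2))
  paths <- write_synthetic_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(utils::read.table(paths["counts"], sep = "\t",
                                      header = TRUE, row.names = 1,
                                      check.names = FALSE))
  expect_equal(back, sim$dataset$counts$values)
  gmt <- strsplit(readLines(paths["gmt"]), "\t")
  expect_setequal(vapply(gmt, `[`, character(1), 1),
                  names(sim$dataset$annotations$sets))
})
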