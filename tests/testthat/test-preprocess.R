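test_that("FPKM follows the 1e9 c / (N L) formula and conserves totals", {
  cnt <- toy_counts(matrix(c(10, 0, 990000, 1e6 - 10, 0, 1e6), 2, 3),
                    lengths = c(1000, 500))
  # place the full library in one gene so N = 1e6 exactly
  cnt$values[2, ] <- 1e6 - cnt$values[1, ]
  fp <- compute_fpkm(cnt)
  expect_equal(fp$values[1, 1], 10)   # 1e9 * 10 / (1e6 * 1000)
  expect_equal(fp$values[1, 3], 0)
  expect_equal(fp$unit, "fpkm")

  set.seed(1)
  rnd <- toy_counts(matrix(rpois(15, 50), 5, 3),
                    lengths = sample(500:2000, 5))
  fpr <- compute_fpkm(rnd)
  lhs <- colSums(fpr$values * rnd$gene_lengths) / 1e9 *
    colSums(rnd$values)
  expect_equal(lhs, colSums(rnd$values), tolerance = 1e-12)

  bad <- rnd; bad$gene_lengths[1] <- 0
  expect_error(compute_fpkm(bad), "zero-length")
  bad2 <- rnd; bad2$values[, 1] <- 0
  expect_error(compute_fpkm(bad2), "zero-library")
})

test_that("replicate QC is computed on log2(FPKM+1) with degenerate guards", {
  v <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2)
  x <- toy_counts(v)
  x$unit <- "fpkm"
  qc <- replicate_qc(x)
  expect_equal(qc$T1[1, 2], 1.0)
  # an all-zero replicate gives missing correlations, not an error
  v2 <- matrix(c(1, 5, 9, 0, 0, 0), 3, 2)
  x2 <- toy_counts(v2); x2$unit <- "fpkm"
  expect_warning(qc2 <- replicate_qc(x2), "constant")
  expect_true(is.na(qc2$T1[1, 2]))
  # NA abundances are imputed as 0 before the transform
  v3 <- matrix(c(1, 5, 9, 1, 5, NA), 3, 2)
  x3 <- toy_counts(v3); x3$unit <- "fpkm"
  qc3 <- replicate_qc(x3)
  expect_equal(qc3$T1[1, 2],
               stats::cor(log2(c(1, 5, 9) + 1), log2(c(1, 5, 0) + 1)))
})

test_that("replicates of the default design are strongly concordant", {
  qc <- replicate_qc(compute_fpkm(default_sim()$dataset$counts))
  rbar <- mean(vapply(qc, function(m) mean(m[upper.tri(m)]), numeric(1)))
  expect_gte(rbar, 0.9)
})

test_that("expressed-gene filter keeps genes peaking at or above 1 FPKM", {
  v <- rbind(c(0, 0, 0, 0, 0),
             c(0.2, 0.4, 1.0, 0.1, 0),
             c(0.9, 0.9, 0.99, 0.5, 0.2))
  x <- toy_counts(v[, rep(1:5, each = 2)])  # 2 identical reps x 5 tps
  x$unit <- "fpkm"
  avg <- average_replicates(x)
  kept <- filter_expressed(avg)
  expect_false("g01" %in% kept)
  expect_true("g02" %in% kept)
  expect_false("g03" %in% kept)

  # planted flat-low genes are nearly all removed
  set.seed(8)
  n <- 1000
  fl <- matrix(runif(200 * 5, 0, 0.45), 200, 5)
  hi <- matrix(rexp(800 * 5, rate = 1 / 20), 800, 5)
  m <- rbind(hi, fl)
  rownames(m) <- sprintf("g%04d", seq_len(n))
  colnames(m) <- paste0("T", 1:5)
  xs <- expr_set(m, unit = "fpkm",
                 sample_meta = data.frame(sample = colnames(m),
                                          timepoint = colnames(m),
                                          replicate = 1))
  kept <- filter_expressed(xs)
  expect_gte(mean(!(sprintf("g%04d", 801:1000) %in% kept)), 0.95)
})

test_that("replicate averaging happens on the FPKM scale, before any log", {
  v <- matrix(c(2, 4, 0, 8), 1, 4)
  x <- toy_counts(v); x$unit <- "fpkm"
  avg <- average_replicates(x)
  expect_equal(unname(avg$values[1, ]), c(3, 4))
  # averaging then log differs from log then averaging: the pipeline
  # must do the former
  expect_equal(log2(avg$values[1, "T2"] + 1), log2(5), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(log2(5), mean(log2(c(0, 8) + 1)))))
})

test_that("BH adjustment matches the step-up hand calculation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p-rank
  expect_true(all(q >= 0 & q <= 1))
})

test_that("NB exact test is symmetric and handles degenerate genes", {
  set.seed(3)
  a <- matrix(rnbinom(60, mu = 40, size = 5), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), paste0("a", 1:3)))
  b <- matrix(rnbinom(60, mu = 40, size = 5), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), paste0("b", 1:3)))
  a[1, ] <- 0; b[1, ] <- 0   # zero-total gene
  r1 <- nb_exact_test(a, b)
  r2 <- nb_exact_test(b, a)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-10)
  expect_equal(r1$logFC, -r2$logFC, tolerance = 1e-10)
  expect_equal(r1$pvalue[1], 1)
  expect_equal(r1$logFC[1], 0)
  same <- nb_exact_test(a, a)
  expect_true(all(same$logFC == 0))
  expect_true(all(same$pvalue == 1))
})

test_that("the Poisson limit reduces to the conditional binomial test", {
  # equal column sums by construction, so library equalisation is a no-op
  binom_two_sided <- function(x, n, p = 0.5) {
    d <- dbinom(0:n, n, p)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
  }
  set.seed(4)
  for (i in 1:25) {
    g1a <- rpois(3, 15); g1b <- rpois(3, 15)
    total <- 200
    a <- rbind(g1 = g1a, filler = total - g1a)
    b <- rbind(g1 = g1b, filler = total - g1b)
    colnames(a) <- paste0("a", 1:3); colnames(b) <- paste0("b", 1:3)
    res <- nb_exact_test(a, b, dispersion_mode = "fixed", dispersion = 0)
    expect_equal(res$pvalue[1],
                 binom_two_sided(sum(g1a), sum(g1a) + sum(g1b)),
                 tolerance = 1e-6)
  }
})

test_that("DE calling applies both the FDR and fold-change thresholds", {
  tab <- data.frame(FDR = c(0.005, 0.005, 0.5, 0.001),
                    logFC = c(log2(3), log2(1.5), log2(8), -log2(4)))
  expect_equal(call_degs(tab), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("PEG/CEG split partitions the DE genes by contrast count", {
  deg <- data.frame(
    gene = c("a", "b", "b", "c", "c", "c", "d"),
    contrast = c("E13.5-E16.5", "E16.5-P0", "P0-P14", "E13.5-E16.5",
                 "P0-P14", "P14-P60", "E16.5-P0"),
    de_flag = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  part <- partition_peg_ceg(deg)
  expect_setequal(part$peg, "a")
  expect_setequal(part$ceg, c("b", "c"))
  expect_equal(length(part$peg) + length(part$ceg),
               length(unique(deg$gene[deg$de_flag])))
  part2 <- partition_peg_ceg(deg, rule = "timepoints")
  expect_setequal(part2$peg, "a")
  expect_setequal(part2$ceg, c("b", "c"))
})

test_that("adjacent-contrast DE recovers a planted knockout", {
  # noise_sd = 0 and regulator_coupling = 0 make the count variation
  # exactly NB with dispersion 0.1, the regime this operation models;
  # extra log-normal noise layers make any NB test tail-anticonservative
  one <- function(s) {
    sim <- simulate_timecourse(sim_config(n_genes = 300, n_tfs = 60,
                                          regulator_coupling = 0,
                                          noise_sd = 0, seed = s))
    master <- unique(sim$truth$regulator_edges$regulator)[1]
    ck <- simulate_cko(sim$truth, sim$dataset, master,
                       effect_size = log(4), n_reps = 3, seed = s + 10)
    de <- nb_exact_test(ck$cko, ck$control)
    de$FDR <- bh_adjust(de$pvalue)
    de$de_flag <- call_degs(de, fdr_max = 0.05, fc_min = 2)
    called <- de$gene[de$de_flag]
    c(sens = mean(ck$de_genes %in% called),
      fdr = if (length(called)) mean(!(called %in% ck$de_genes)) else 0)
  }
  res <- vapply(1:8, one, numeric(2))
  expect_gte(mean(res["sens", ]), 0.8)
  expect_lte(mean(res["fdr", ]), 0.1)
})
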