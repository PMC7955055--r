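# Shared fixtures and independent oracles. Everything is generated in
# code; expensive pipeline stages are memoised for the duration of a run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fun(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-condition synthetic dataset (the study design: 5 timepoints,
# 3/3/3/2/3 replicates, 4 modules, noise_sd 0.2)
default_sim <- function() cached("sim", function()
  simulate_timecourse(sim_config(seed = 1)))

default_avg_fpkm <- function() cached("avg", function()
  average_replicates(compute_fpkm(default_sim()$dataset$counts)))

default_log2 <- function() cached("lg", function()
  log2(default_avg_fpkm()$values + 1))

# module assignment recovered from the default dataset (restricted to
# planted module genes, as the CEG stage would deliver)
default_modules <- function() cached("modules", function() {
  sim <- default_sim()
  lg <- default_log2()
  mg <- names(sim$truth$module_of_gene)[!is.na(sim$truth$module_of_gene)]
  tom <- tom_similarity(abs(stats::cor(t(lg[mg, ])))^12)
  detect_modules(tom, lg[mg, ])
})

default_tfs <- function() {
  sim <- default_sim()
  intersect(sim$dataset$tf_ids,
            names(sim$truth$module_of_gene)[
              !is.na(sim$truth$module_of_gene)])
}

default_pair_table <- function() cached("pairs", function()
  build_pair_table(default_avg_fpkm()$values, default_tfs()))

default_training <- function() cached("training", function()
  build_training_sets(default_modules(), default_sim()$dataset$annotations,
                      default_tfs(), seed = 1))

default_fit <- function() cached("fit", function()
  train_and_score(default_pair_table(), default_training(),
                  prior_edges = default_sim()$dataset$prior_edges,
                  seed = 1))

# a small expr_set of counts built by hand
toy_counts <- function(values, lengths = NULL) {
  g <- sprintf("g%02d", seq_len(nrow(values)))
  s <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(g, s)
  if (is.null(lengths)) lengths <- stats::setNames(rep(1000, nrow(values)), g)
  else names(lengths) <- g
  meta <- data.frame(sample = s,
                     timepoint = paste0("T", ceiling(seq_along(s) / 2)),
                     replicate = rep_len(1:2, length(s)))
  expr_set(values, unit = "counts", sample_meta = meta,
           gene_lengths = lengths)
}

# ---- independent oracles ------------------------------------------------

# triple-loop TOM oracle
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exact hypergeometric upper tail by summed point masses
hyper_upper_oracle <- function(k, m_in, m_out, draws) {
  if (k <= 0) return(1)
  jmax <- min(m_in, draws)
  if (k > jmax) return(0)
  sum(exp(lchoose(m_in, k:jmax) + lchoose(m_out, draws - (k:jmax)) -
            lchoose(m_in + m_out, draws)))
}

# exhaustive best cohesiveness over all vertex subsets
cohesiveness_optimum <- function(edges, penalty) {
  A <- tfnetdev:::.edge_adjacency(edges)
  n <- ncol(A)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    V <- colnames(A)[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    f <- tfnetdev:::.cohesiveness(A, V, penalty)
    if (f > best) best <- f
  }
  best
}

# deterministic set of small weighted graphs for the partition oracle
fixture_graphs <- function() {
  set.seed(20240915)
  out <- list()
  while (length(out) < 10) {
    n <- sample(4:7, 1)
    nodes <- letters[seq_len(n)]
    full <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(full)) < stats::runif(1, 0.4, 0.9)
    if (sum(keep) < 3) next
    out[[length(out) + 1]] <- data.frame(
      tf_a = full[keep, 1], tf_b = full[keep, 2],
      weight = round(stats::runif(sum(keep), 0.1, 1), 2))
  }
  out
}

# planted linear regulator -> target data for directed GRN recovery
linear_grn_data <- function(seed, n_reg = 10, n_tgt = 50, k_true = 3,
                            n_obs = 40, noise_sd = 0.3) {
  set.seed(seed)
  regs <- matrix(stats::rnorm(n_reg * n_obs), n_reg, n_obs,
                 dimnames = list(paste0("r", seq_len(n_reg)), NULL))
  tg <- matrix(0, n_tgt, n_obs,
               dimnames = list(paste0("t", seq_len(n_tgt)), NULL))
  truth <- matrix(FALSE, n_reg, n_tgt,
                  dimnames = list(rownames(regs), rownames(tg)))
  for (j in seq_len(n_tgt)) {
    pick <- sample(n_reg, k_true)
    coefs <- stats::runif(k_true, 0.5, 1.5) *
      sample(c(-1, 1), k_true, replace = TRUE)
    tg[j, ] <- colSums(regs[pick, , drop = FALSE] * coefs) +
      stats::rnorm(n_obs, 0, noise_sd)
    truth[pick, j] <- TRUE
  }
  list(expr = rbind(regs, tg), regulators = rownames(regs),
       targets = rownames(tg), truth = truth)
}

# AUROC of GRN edge weights against the planted adjacency
grn_auroc <- function(grn, truth) {
  lab <- truth[cbind(grn$edges$regulator, grn$edges$target)]
  as.numeric(pROC::auc(pROC::roc(response = lab,
                                 predictor = grn$edges$weight,
                                 quiet = TRUE, direction = "<")))
}

# markov chain x -> y -> z with gaussian noise
markov_chain_data <- function(seed, n = 200, noise = 0.5) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- x + stats::rnorm(n, 0, noise)
  z <- y + stats::rnorm(n, 0, noise)
  rbind(x = x, y = y, z = z)
}

# the CKO -> DE -> directed-GRN hub pipeline on a compact design
run_cko_pipeline <- function(seed, n_genes = 400, n_tfs = 80,
                             n_reps = 8) {
  sim <- simulate_timecourse(sim_config(n_genes = n_genes, n_tfs = n_tfs,
                                        seed = seed))
  ds <- sim$dataset; tr <- sim$truth
  master <- unique(tr$regulator_edges$regulator)[1]
  ck <- simulate_cko(tr, ds, master, effect_size = log(4),
                     n_reps = n_reps, seed = seed + 1000)
  de <- nb_exact_test(ck$cko, ck$control)
  de$FDR <- bh_adjust(de$pvalue)
  deg <- de$gene[de$FDR < 0.05 & abs(de$logFC) > 1]
  cnt <- cbind(ck$control, ck$cko)
  lf <- log2(1e9 * sweep(sweep(cnt, 2, colSums(cnt), "/"), 1,
                         ds$counts$gene_lengths, "/") + 1)
  # the knocked TF is excluded from the candidate regulators: its
  # expression in the knockout arm is a genotype artifact
  regs <- setdiff(intersect(deg, ds$tf_ids), master)
  grn <- if (length(regs) >= 2 && length(deg) >= 3)
    genie3_grn(lf[deg, , drop = FALSE], regulators = regs, targets = deg,
               n_trees = 500, seed = seed)
  else NULL
  tgts <- tr$regulator_edges$target[tr$regulator_edges$regulator == master]
  outdeg <- table(factor(tr$regulator_edges$regulator, levels = tgts))
  list(planted_de = ck$de_genes, called_de = deg,
       sensitivity = mean(ck$de_genes %in% deg),
       observed_fdr = if (length(deg)) mean(!(deg %in% ck$de_genes)) else 0,
       hub = names(which.max(outdeg)),
       top3 = if (is.null(grn)) NA else
         names(which.max(outdeg)) %in% rank_hubs(grn)$node[1:3])
}
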