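#' Simulation configuration
#'
#' Parameters of the synthetic developmental time-course generator. The
#' defaults emulate a five-timepoint, 2-3-replicate bulk RNA-seq design
#' with planted co-expression modules, planted TF functional groups and
#' planted regulator->target effects.
#'
#' @param n_genes number of genes.
#' @param n_tfs number of genes flagged as transcription factors
#'   (`<= n_genes`); TFs are spread evenly over modules and the flat pool.
#' @param n_timepoints number of timepoints (>= 3).
#' @param replicates_per_timepoint integer vector of replicate counts, one
#'   per timepoint. The default gives the fourth timepoint only two
#'   replicates so the replicate-averaging path with unequal counts is
#'   always exercised.
#' @param timepoint_labels optional labels; defaults to the five classic
#'   murine striatal stages for 5 timepoints, else `T1..Tn`.
#' @param n_modules number of planted co-expression modules (>= 2).
#' @param module_fraction fraction of genes assigned to modules; the rest
#'   are flat background genes belonging to no module.
#' @param trend_shapes shapes cycled over modules; subset of
#'   `"monotone-up"`, `"monotone-down"`, `"peak"`, `"valley"`.
#' @param mirror_fraction fraction of each module's genes following the
#'   mirrored (sign-flipped) trend, so modules contain both positively and
#'   negatively correlated members.
#' @param amplitude_log2 peak-to-trough amplitude of module trends, log2
#'   units.
#' @param nb_dispersion negative-binomial dispersion of counts (0 gives
#'   Poisson sampling).
#' @param library_size_mean mean sequencing depth per sample.
#' @param gene_length_range min/max transcript length in bp.
#' @param noise_sd per-gene, per-sample biological noise on the log2
#'   scale; regulator noise propagates to targets (see Details).
#' @param regulator_coupling multiplier on the regulator noise deviation
#'   inherited by each target.
#' @param seed integer seed; identical configs reproduce bit-identical
#'   datasets.
#'
#' @details Each module carries a piecewise-linear latent trend over the
#' timepoint index. Per module, one "master" TF regulates a secondary
#' "hub" TF plus a set of module genes, and the hub regulates a subset of
#' the master's targets: regulator->target edges are causal in the
#' generative model, because each target's log2 mean inherits its
#' regulators' biological-noise deviations (recursively, the edge set is
#' acyclic). Counts are drawn negative-binomial with mean proportional to
#' trend x gene length x library-size factor, with per-sample column sums
#' scaled to the planted library size.
#'
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_tfs = 200, n_timepoints = 5,
                       replicates_per_timepoint = c(3, 3, 3, 2, 3),
                       timepoint_labels = NULL,
                       n_modules = 4, module_fraction = 0.6,
                       trend_shapes = c("monotone-up", "monotone-down",
                                        "peak", "valley"),
                       mirror_fraction = 0.3, amplitude_log2 = 3,
                       nb_dispersion = 0.1, library_size_mean = 2e6,
                       gene_length_range = c(500, 5000), noise_sd = 0.2,
                       regulator_coupling = 2, seed = 1) {
  if (n_genes < 1 || n_tfs < 1 || n_tfs > n_genes)
    stop("need 1 <= n_tfs <= n_genes")
  if (n_timepoints < 3) stop("need >= 3 timepoints")
  if (length(replicates_per_timepoint) != n_timepoints)
    stop("replicates_per_timepoint must have one entry per timepoint")
  if (any(replicates_per_timepoint < 2)) stop("need >= 2 replicates")
  if (n_modules < 2) stop("need >= 2 modules")
  if (n_modules > n_genes) stop("more modules than genes")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  shapes <- match.arg(trend_shapes,
                      c("monotone-up", "monotone-down", "peak", "valley",
                        "flat"), several.ok = TRUE)
  if (is.null(timepoint_labels))
    timepoint_labels <- if (n_timepoints == 5)
      c("E13.5", "E16.5", "P0", "P14", "P60") else
      paste0("T", seq_len(n_timepoints))
  structure(list(n_genes = n_genes, n_tfs = n_tfs,
                 n_timepoints = n_timepoints,
                 replicates_per_timepoint = replicates_per_timepoint,
                 timepoint_labels = timepoint_labels,
                 n_modules = n_modules, module_fraction = module_fraction,
                 trend_shapes = shapes, mirror_fraction = mirror_fraction,
                 amplitude_log2 = amplitude_log2,
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 gene_length_range = gene_length_range,
                 noise_sd = noise_sd,
                 regulator_coupling = regulator_coupling, seed = seed),
            class = "sim_config")
}

# Piecewise-linear latent trend templates over the timepoint index,
# scaled to [0, 1] and interpolated to n timepoints. The anchors are
# deliberately asymmetric (convex rise, convex decay, early peak, late
# valley): no template is an affine image of another's negation, so
# modules remain distinguishable under an unsigned |cor| adjacency even
# though each module mixes positively and negatively correlated members.
.trend_template <- function(shape, n) {
  anchors <- switch(shape,
                    "monotone-up" = c(0, 0.05, 0.15, 0.4, 1),
                    "monotone-down" = c(1, 0.4, 0.15, 0.05, 0),
                    "peak" = c(0.2, 1, 0.5, 0.15, 0),
                    "valley" = c(0.9, 0.4, 0, 0.25, 0.75),
                    "flat" = rep(0.5, 5),
                    stop("unknown trend shape"))
  stats::approx(seq(0, 1, length.out = 5), anchors,
                xout = seq(0, 1, length.out = n))$y
}

# run fun() under a local RNG state derived from seed
.with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fun()
}

#' Simulate a developmental time-course count dataset with planted truth
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (class `synthetic_dataset`: counts
#'   as an [expr_set], `tf_ids`, `annotations`, `prior_edges`, and the
#'   planted per-sample `library_sizes`) and `truth` (class
#'   `planted_truth`: `module_of_gene`, `module_trend`, `mirror_of_gene`,
#'   `functional_groups`, `regulator_edges`, `de_genes_per_contrast`,
#'   `log2_mean` of the noise-free expression).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, function() .simulate_timecourse_impl(config))
}

.simulate_timecourse_impl <- function(cfg) {
  G <- cfg$n_genes; Tn <- cfg$n_timepoints
  genes <- sprintf("g%04d", seq_len(G))
  # spread TFs evenly through the gene list so every module gets some
  tf_idx <- unique(round(seq(1, G, length.out = cfg$n_tfs)))
  tfs <- genes[tf_idx]
  is_tf <- genes %in% tfs

  # module assignment: first module_fraction of genes, round-robin
  n_mod_genes <- round(cfg$module_fraction * G)
  module <- rep(NA_integer_, G)
  module[seq_len(n_mod_genes)] <- rep_len(seq_len(cfg$n_modules),
                                          n_mod_genes)
  names(module) <- genes
  shapes <- rep_len(setdiff(cfg$trend_shapes, "flat"), cfg$n_modules)
  names(shapes) <- paste0("M", seq_len(cfg$n_modules))

  mirrored <- rep(FALSE, G)
  for (m in seq_len(cfg$n_modules)) {
    idx <- which(module == m)
    k <- floor(cfg$mirror_fraction * length(idx))
    if (k > 0) mirrored[idx[seq_len(k)]] <- TRUE
  }

  # per-gene baseline (log2 FPKM-like scale, wide dynamic range as in
  # bulk RNA-seq) and amplitude
  base <- stats::rnorm(G, mean = 3.5, sd = 2)
  amp <- cfg$amplitude_log2 * stats::runif(G, 0.7, 1.3)
  gene_lengths <- round(stats::runif(G, cfg$gene_length_range[1],
                                     cfg$gene_length_range[2]))
  names(gene_lengths) <- genes

  # noise-free log2 expression over timepoints
  log2_mean <- matrix(base, G, Tn)
  for (m in seq_len(cfg$n_modules)) {
    tmpl <- .trend_template(shapes[m], Tn) - 0.5
    idx <- which(module == m)
    sgn <- ifelse(mirrored[idx], -1, 1)
    log2_mean[idx, ] <- log2_mean[idx, ] +
      outer(amp[idx] * sgn, tmpl)
  }
  dimnames(log2_mean) <- list(genes, cfg$timepoint_labels)

  # planted regulator edges: per module a master TF drives a hub TF plus
  # module genes; the hub drives a subset of the master's targets
  edges <- list()
  groups <- list()
  for (m in seq_len(cfg$n_modules)) {
    mod_genes <- genes[which(module == m)]
    mod_tfs <- intersect(tfs, mod_genes)
    if (length(mod_tfs) >= 2)
      groups[[paste0("planted_fg_", m)]] <- mod_tfs
    if (length(mod_tfs) < 2 || length(mod_genes) < 6) next
    master <- mod_tfs[1]; hub <- mod_tfs[2]
    pool_tf <- setdiff(mod_tfs, c(master, hub))
    pool_non <- setdiff(mod_genes, c(mod_tfs, master, hub))
    # a few TF targets act as competing regulator candidates; the bulk
    # of the shared targets are non-TFs, and the hub's own targets are
    # drawn from those so that only the hub carries their extra signal
    tgt <- c(utils::head(pool_tf, 3),
             utils::head(pool_non, min(9, length(pool_non))))
    hub_tgt <- utils::head(intersect(tgt, pool_non), 8)
    if (length(hub_tgt) == 0) hub_tgt <- utils::head(tgt, 8)
    sgn_m <- sample(c(1, -1), length(tgt) + 1, replace = TRUE,
                    prob = c(0.7, 0.3))
    edges[[length(edges) + 1]] <- data.frame(
      regulator = master, target = c(hub, tgt),
      sign = sgn_m, effect = log(2), stringsAsFactors = FALSE)
    edges[[length(edges) + 1]] <- data.frame(
      regulator = hub, target = hub_tgt,
      sign = sample(c(1, -1), length(hub_tgt), replace = TRUE,
                    prob = c(0.7, 0.3)),
      effect = log(2), stringsAsFactors = FALSE)
  }
  regulator_edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(regulator = character(0), target = character(0),
               sign = numeric(0), effect = numeric(0))

  # samples
  reps <- cfg$replicates_per_timepoint
  sample_meta <- do.call(rbind, lapply(seq_len(Tn), function(i)
    data.frame(sample = sprintf("%s_r%d", cfg$timepoint_labels[i],
                                seq_len(reps[i])),
               timepoint = cfg$timepoint_labels[i],
               replicate = seq_len(reps[i]))))
  sample_meta$timepoint <- factor(sample_meta$timepoint,
                                  levels = cfg$timepoint_labels)
  S <- nrow(sample_meta)
  lib_sizes <- round(cfg$library_size_mean *
                       exp(stats::rnorm(S, 0, 0.1)))
  names(lib_sizes) <- sample_meta$sample

  # per-gene x sample biological noise; regulator deviations propagate to
  # targets (edge set is acyclic: master -> hub -> leaves)
  z <- matrix(stats::rnorm(G * S, 0, cfg$noise_sd), G, S,
              dimnames = list(genes, sample_meta$sample))
  dev <- .propagate_dev(z, regulator_edges, cfg$regulator_coupling)

  counts <- .sample_counts(log2_mean, dev, sample_meta, gene_lengths,
                           lib_sizes, cfg$nb_dispersion)
  em <- expr_set(counts, unit = "counts", sample_meta = sample_meta,
                 gene_lengths = gene_lengths)

  truth <- structure(list(
    module_of_gene = module,
    module_trend = shapes,
    mirror_of_gene = stats::setNames(mirrored, genes),
    functional_groups = groups,
    regulator_edges = regulator_edges,
    de_genes_per_contrast = list(),
    log2_mean = log2_mean), class = "planted_truth")

  ann <- simulate_annotations(truth, n_decoy_terms = 20, decoy_size = 8,
                              mislabel_rate = 0, seed = cfg$seed + 101,
                              tf_pool = tfs, universe = genes)
  priors <- if (length(groups))
    simulate_prior_edges(truth, recall = 0.5, precision = 0.9,
                         seed = cfg$seed + 202, tf_pool = tfs) else
    data.frame(tf_a = character(0), tf_b = character(0))

  dataset <- structure(list(counts = em, tf_ids = tfs, annotations = ann,
                            prior_edges = priors,
                            library_sizes = lib_sizes,
                            config = cfg), class = "synthetic_dataset")
  list(dataset = dataset, truth = truth)
}

# Propagate each regulator's expression deviation to its targets in
# topological order (the planted edge set is acyclic), scaled by the
# coupling constant and the edge sign.
.propagate_dev <- function(z, edges, coupling) {
  dev <- z
  if (nrow(edges) == 0 || coupling == 0) return(dev)
  remaining <- edges
  done <- setdiff(rownames(z), edges$target)
  for (pass in seq_len(nrow(edges))) {
    for (t in unique(remaining$target)) {
      e <- remaining[remaining$target == t, , drop = FALSE]
      if (!all(e$regulator %in% done)) next
      for (j in seq_len(nrow(e)))
        dev[t, ] <- dev[t, ] + coupling * e$sign[j] * dev[e$regulator[j], ]
      done <- c(done, t)
      remaining <- remaining[remaining$target != t, , drop = FALSE]
    }
    if (nrow(remaining) == 0) break
  }
  dev
}

# NB (or Poisson) counts with expected column sums equal to lib_sizes
.sample_counts <- function(log2_mean, dev, sample_meta, gene_lengths,
                           lib_sizes, dispersion) {
  tp <- as.character(sample_meta$timepoint)
  mu_expr <- 2^(log2_mean[, tp, drop = FALSE] + dev)  # FPKM-like scale
  mu <- mu_expr * (gene_lengths / 1e3)                # per-kb -> per-gene
  mu <- sweep(mu, 2, lib_sizes / colSums(mu), "*")    # planted depth
  G <- nrow(mu); S <- ncol(mu)
  counts <- if (dispersion > 0)
    matrix(stats::rnbinom(G * S, mu = mu, size = 1 / dispersion), G, S)
  else matrix(stats::rpois(G * S, lambda = mu), G, S)
  dimnames(counts) <- list(rownames(log2_mean), sample_meta$sample)
  counts
}

#' Simulate an annotation collection from planted functional groups
#'
#' Returns the planted TF functional groups (with an optional fraction of
#' members swapped for random TFs) plus decoy terms of random TFs, over a
#' declared gene universe.
#'
#' @param truth `planted_truth` with >= 1 functional group.
#' @param n_decoy_terms number of decoy terms.
#' @param decoy_size members per decoy term.
#' @param mislabel_rate fraction in [0, 1) of each group's members
#'   replaced by random TFs outside the group.
#' @param seed integer seed.
#' @param tf_pool candidate TFs for mislabelling/decoys (defaults to the
#'   union of group members).
#' @param universe gene universe (defaults to `tf_pool`).
#' @return list of class `annotation_collection`: `sets` (term -> gene
#'   vector) and `universe`.
#' @export
simulate_annotations <- function(truth, n_decoy_terms, decoy_size,
                                 mislabel_rate, seed, tf_pool = NULL,
                                 universe = NULL) {
  if (length(truth$functional_groups) < 1)
    stop("truth has no functional groups")
  if (mislabel_rate < 0 || mislabel_rate >= 1)
    stop("mislabel_rate must be in [0, 1)")
  if (is.null(tf_pool)) tf_pool <- unique(unlist(truth$functional_groups))
  if (n_decoy_terms > 0 && decoy_size > length(tf_pool))
    stop("decoy_size larger than the TF pool")
  if (is.null(universe)) universe <- tf_pool
  .with_seed(seed, function() {
    sets <- truth$functional_groups
    for (nm in names(sets)) {
      g <- sets[[nm]]
      k <- round(mislabel_rate * length(g))
      if (k > 0) {
        out_pool <- setdiff(tf_pool, g)
        swap_in <- sample(out_pool, min(k, length(out_pool)))
        drop <- sample(g, length(swap_in))
        sets[[nm]] <- union(setdiff(g, drop), swap_in)
      }
    }
    if (n_decoy_terms > 0)
      for (i in seq_len(n_decoy_terms))
        sets[[sprintf("decoy_%02d", i)]] <- sample(tf_pool, decoy_size)
    structure(list(sets = sets, universe = universe),
              class = "annotation_collection")
  })
}

# canonical undirected pair key: smaller id first
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# all unordered within-group pairs as a two-column data.frame
.within_group_pairs <- function(groups) {
  pairs <- list()
  for (g in groups) {
    g <- sort(unique(g))
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    pairs[[length(pairs) + 1]] <- data.frame(tf_a = cmb[1, ],
                                             tf_b = cmb[2, ])
  }
  if (!length(pairs)) return(data.frame(tf_a = character(0),
                                        tf_b = character(0)))
  out <- unique(do.call(rbind, pairs))
  rownames(out) <- NULL
  out
}

#' Simulate a prior TF-TF interaction edge list
#'
#' Draws `recall` of all within-group TF pairs as true priors and pads
#' with false pairs (never within any group) so that
#' true/(true+false) = `precision`.
#'
#' @param truth `planted_truth` with >= 1 co-functional TF pair.
#' @param recall,precision in (0, 1].
#' @param seed integer seed.
#' @param tf_pool pool from which false pairs are drawn (defaults to the
#'   union of group members).
#' @return data.frame with columns `tf_a`, `tf_b` (undirected, `tf_a <
#'   tf_b`) and `true_prior` flag.
#' @export
simulate_prior_edges <- function(truth, recall, precision, seed,
                                 tf_pool = NULL) {
  if (length(truth$functional_groups) < 1) stop("no functional groups")
  if (recall <= 0 || recall > 1 || precision <= 0 || precision > 1)
    stop("recall and precision must be in (0, 1]")
  wg <- .within_group_pairs(truth$functional_groups)
  if (nrow(wg) == 0) stop("no co-functional TF pair in truth")
  if (is.null(tf_pool)) tf_pool <- unique(unlist(truth$functional_groups))
  .with_seed(seed, function() {
    n_true <- round(recall * nrow(wg))
    true_pairs <- wg[sample(nrow(wg), n_true), , drop = FALSE]
    n_false <- round(n_true * (1 - precision) / precision)
    wg_keys <- .pair_key(wg$tf_a, wg$tf_b)
    false_pairs <- data.frame(tf_a = character(0), tf_b = character(0))
    guard <- 0
    while (nrow(false_pairs) < n_false && guard < 100 * (n_false + 1)) {
      guard <- guard + 1
      cand <- sample(tf_pool, 2)
      key <- .pair_key(cand[1], cand[2])
      if (key %in% wg_keys) next
      if (nrow(false_pairs) &&
          key %in% .pair_key(false_pairs$tf_a, false_pairs$tf_b)) next
      false_pairs <- rbind(false_pairs,
                           data.frame(tf_a = min(cand), tf_b = max(cand)))
    }
    out <- rbind(
      data.frame(tf_a = pmin(true_pairs$tf_a, true_pairs$tf_b),
                 tf_b = pmax(true_pairs$tf_a, true_pairs$tf_b),
                 true_prior = TRUE),
      cbind(false_pairs, true_prior = logical(nrow(false_pairs))))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a conditional-knockout contrast
#'
#' Resamples control counts from the dataset's generative model at one
#' timepoint, then produces a CKO matrix in which the knocked TF's mean is
#' set to ~0 and each of its direct targets' means is multiplied by
#' `exp(sign * effect_size)`. Indirect (grand-)targets are untouched.
#'
#' @param truth,dataset output of [simulate_timecourse()].
#' @param knocked_tf gene id; must have outgoing regulator edges.
#' @param effect_size log-scale effect on direct targets (> 0; 0 makes the
#'   knocked TF itself the only planted DE gene).
#' @param timepoint timepoint label at which the contrast is simulated
#'   (default: the middle timepoint).
#' @param n_reps replicates per arm, default 3.
#' @param seed integer seed.
#' @return list with `control` and `cko` count matrices, the updated
#'   `truth` (planted DE genes recorded under
#'   `de_genes_per_contrast[[paste0(knocked_tf, "_cko")]]`), and
#'   `de_genes` for convenience.
#' @export
simulate_cko <- function(truth, dataset, knocked_tf, effect_size,
                         timepoint = NULL, n_reps = 3, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  ed <- truth$regulator_edges
  if (!(knocked_tf %in% ed$regulator))
    stop(sprintf("'%s' has no outgoing regulator edges", knocked_tf))
  if (effect_size < 0) stop("effect_size must be >= 0")
  cfg <- dataset$config
  if (is.null(timepoint))
    timepoint <- cfg$timepoint_labels[ceiling(cfg$n_timepoints / 2)]
  tp_i <- match(timepoint, cfg$timepoint_labels)
  if (is.na(tp_i)) stop("unknown timepoint")
  .with_seed(seed, function() {
    genes <- rownames(truth$log2_mean)
    lm_tp <- truth$log2_mean[, tp_i]
    tgt <- ed[ed$regulator == knocked_tf, , drop = FALSE]
    one_arm <- function(shift) {
      lm2 <- lm_tp + shift
      meta <- data.frame(sample = paste0("s", seq_len(n_reps)),
                         timepoint = timepoint,
                         replicate = seq_len(n_reps))
      z <- matrix(stats::rnorm(length(genes) * n_reps, 0, cfg$noise_sd),
                  length(genes), n_reps,
                  dimnames = list(genes, meta$sample))
      dev <- .propagate_dev(z, truth$regulator_edges,
                            cfg$regulator_coupling)
      libs <- stats::setNames(round(cfg$library_size_mean *
                                      exp(stats::rnorm(n_reps, 0, 0.1))),
                              meta$sample)
      .sample_counts(matrix(lm2, length(genes), 1,
                            dimnames = list(genes, timepoint)),
                     dev, meta, dataset$counts$gene_lengths, libs,
                     cfg$nb_dispersion)
    }
    ctrl <- one_arm(stats::setNames(rep(0, length(genes)), genes))
    # losing an activator lowers its positively regulated targets
    shift <- stats::setNames(rep(0, length(genes)), genes)
    shift[tgt$target] <- -tgt$sign * effect_size / log(2)  # log2 units
    shift[knocked_tf] <- -30                               # mean ~ 0
    cko <- one_arm(shift)
    colnames(ctrl) <- paste0("ctrl_", seq_len(n_reps))
    colnames(cko) <- paste0("cko_", seq_len(n_reps))
    de <- if (effect_size > 0) c(knocked_tf, tgt$target) else knocked_tf
    truth$de_genes_per_contrast[[paste0(knocked_tf, "_cko")]] <-
      stats::setNames(c(-1, if (effect_size > 0) -tgt$sign),
                      de)
    list(control = ctrl, cko = cko, truth = truth, de_genes = de)
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Counts, sample metadata and gene lengths as TSV, annotations as GMT,
#' prior edges as TSV, and the planted truth plus seed as a JSON sidecar.
#'
#' @param sim output of [simulate_timecourse()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset; tr <- sim$truth
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "sample_meta.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"),
             gmt = file.path(dir, "annotations.gmt"),
             priors = file.path(dir, "prior_edges.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(ds$counts$values, paths["counts"], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(ds$counts$sample_meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(ds$counts$gene_lengths),
                                length = ds$counts$gene_lengths),
                     paths["lengths"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt <- vapply(names(ds$annotations$sets), function(nm)
    paste(c(nm, nm, ds$annotations$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(gmt, paths["gmt"])
  utils::write.table(ds$prior_edges, paths["priors"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json <- list(
    seed = ds$config$seed,
    module_of_gene = as.list(tr$module_of_gene),
    functional_groups = tr$functional_groups,
    regulator_edges = tr$regulator_edges,
    de_genes_per_contrast = tr$de_genes_per_contrast)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
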