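#' Assemble training pairs from module-level annotation enrichment
#'
#' For each detected module, annotation terms enriched at BH-adjusted
#' hypergeometric p < `fdr` are found. Positive pairs are within-module
#' TF pairs sharing at least one enriched term; negative pairs join TFs
#' annotated to distinct enriched terms of different modules, subsampled
#' to the positive-set size.
#'
#' @param modules `module_assignment` from [detect_modules()].
#' @param annotations `annotation_collection`.
#' @param tf_list TF gene ids; only TF pairs are labelled.
#' @param fdr enrichment threshold, default 0.05.
#' @param seed seed for the negative-pair subsample.
#' @return list of class `training_set`: `positives`, `negatives`
#'   (data.frames `tf_a`, `tf_b`, `provenance`), `enriched_terms`
#'   (module -> term ids).
#' @export
build_training_sets <- function(modules, annotations, tf_list,
                                fdr = 0.05, seed = 1) {
  mods <- setdiff(unique(modules$module), "grey")
  if (length(mods) < 2) stop("need >= 2 non-grey modules")
  if (length(annotations$sets) == 0) stop("empty annotation collection")
  universe <- annotations$universe
  enriched <- list()
  for (m in mods) {
    members <- names(modules$module)[modules$module == m]
    res <- hypergeometric_enrichment(members, annotations,
                                     universe = universe)
    enriched[[m]] <- res$term[res$padj < fdr]
  }
  if (all(lengths(enriched) == 0))
    stop("no module has an enriched term at the requested FDR; ",
         "check the annotation collection and universe")
  # positives: within-module TF pairs sharing an enriched term
  pos <- list()
  for (m in mods) {
    members <- intersect(names(modules$module)[modules$module == m],
                         tf_list)
    for (term in enriched[[m]]) {
      tfs <- sort(intersect(members, annotations$sets[[term]]))
      if (length(tfs) < 2) next
      cmb <- utils::combn(tfs, 2)
      pos[[length(pos) + 1]] <- data.frame(
        tf_a = cmb[1, ], tf_b = cmb[2, ],
        provenance = paste(m, term, sep = ":"))
    }
  }
  if (!length(pos)) stop("no positive pair could be constructed")
  positives <- do.call(rbind, pos)
  positives <- positives[!duplicated(.pair_key(positives$tf_a,
                                               positives$tf_b)), ,
                         drop = FALSE]
  pos_keys <- .pair_key(positives$tf_a, positives$tf_b)
  # negatives: TFs annotated to distinct enriched terms of different
  # modules
  neg <- list()
  for (i in seq_along(mods)) for (j in seq_along(mods)) {
    if (i >= j) next
    mi <- mods[i]; mj <- mods[j]
    for (ti in enriched[[mi]]) for (tj in enriched[[mj]]) {
      if (ti == tj) next
      tfa <- intersect(intersect(names(modules$module)[
        modules$module == mi], tf_list), annotations$sets[[ti]])
      tfb <- intersect(intersect(names(modules$module)[
        modules$module == mj], tf_list), annotations$sets[[tj]])
      if (!length(tfa) || !length(tfb)) next
      grid <- expand.grid(a = tfa, b = tfb, stringsAsFactors = FALSE)
      neg[[length(neg) + 1]] <- data.frame(
        tf_a = pmin(grid$a, grid$b), tf_b = pmax(grid$a, grid$b),
        provenance = paste(mi, ti, "x", mj, tj, sep = ":"))
    }
  }
  if (!length(neg)) stop("no negative pair could be constructed")
  negatives <- do.call(rbind, neg)
  negatives <- negatives[negatives$tf_a != negatives$tf_b, , drop = FALSE]
  neg_keys <- .pair_key(negatives$tf_a, negatives$tf_b)
  negatives <- negatives[!duplicated(neg_keys) &
                           !(neg_keys %in% pos_keys), , drop = FALSE]
  negatives <- .with_seed(seed, function() {
    k <- min(nrow(negatives), nrow(positives))
    negatives[sample(nrow(negatives), k), , drop = FALSE]
  })
  rownames(positives) <- rownames(negatives) <- NULL
  structure(list(positives = positives, negatives = negatives,
                 enriched_terms = enriched), class = "training_set")
}

# feature matrix for a set of pair keys, from a pair_table + priors
.pair_features <- function(pairs, prior_keys) {
  f <- as.matrix(pairs[, c("jaccard", "pcc01", "mi", "bayes", "apex")])
  prior <- as.integer(.pair_key(pairs$tf_a, pairs$tf_b) %in% prior_keys)
  cbind(f, prior = prior)
}

#' Train the TF-interaction classifier and score the pair table
#'
#' A tree-ensemble classifier (random forest, 500 trees; an SVM with a
#' radial kernel is available behind the same interface) is trained on
#' the five co-expression features plus a binary prior-evidence feature.
#' A stratified 5-fold cross-validated ROC/AUC is reported; training
#' pairs receive their out-of-fold probabilities and all remaining
#' retained pairs the full-model probability.
#'
#' @param pairs `pair_table` from [build_pair_table()] (must contain all
#'   training pairs).
#' @param training `training_set`.
#' @param prior_edges optional data.frame with columns `tf_a`, `tf_b`.
#' @param seed integer seed.
#' @param n_trees default 500.
#' @param classifier `"rf"` (default) or `"svm"`.
#' @param n_folds CV folds, default 5.
#' @return list of class `tf_classifier`: `model`, `scores` (the pair
#'   table with `prior`, `probability` and `retained`), `cv_auc`,
#'   `cv_roc` (data.frame of pooled out-of-fold labels/probabilities),
#'   `classifier`, `seed`.
#' @export
train_and_score <- function(pairs, training, prior_edges = NULL, seed = 1,
                            n_trees = 500, classifier = c("rf", "svm"),
                            n_folds = 5) {
  classifier <- match.arg(classifier)
  if (nrow(training$positives) == 0 || nrow(training$negatives) == 0)
    stop("training set needs both classes")
  prior_keys <- if (is.null(prior_edges)) character(0) else
    .pair_key(prior_edges$tf_a, prior_edges$tf_b)
  all_keys <- .pair_key(pairs$tf_a, pairs$tf_b)
  tr_pairs <- rbind(training$positives[, c("tf_a", "tf_b")],
                    training$negatives[, c("tf_a", "tf_b")])
  tr_keys <- .pair_key(tr_pairs$tf_a, tr_pairs$tf_b)
  idx <- match(tr_keys, all_keys)
  if (anyNA(idx))
    stop("training pairs missing from the pair table; score all pairs ",
         "before training")
  y <- factor(rep(c("pos", "neg"),
                  c(nrow(training$positives), nrow(training$negatives))),
              levels = c("neg", "pos"))
  X <- .pair_features(pairs[idx, , drop = FALSE], prior_keys)
  fit_one <- function(Xtr, ytr, s) {
    .with_seed(s, function() {
      if (classifier == "rf")
        randomForest::randomForest(Xtr, ytr, ntree = n_trees)
      else
        e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE)
    })
  }
  prob_of <- function(model, Xn) {
    if (classifier == "rf")
      stats::predict(model, Xn, type = "prob")[, "pos"]
    else
      attr(stats::predict(model, Xn, probability = TRUE),
           "probabilities")[, "pos"]
  }
  folds <- .with_seed(seed, function() {
    f <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    f
  })
  oof <- numeric(length(y))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) stop("degenerate CV fold")
    mk <- fit_one(X[tr, , drop = FALSE], y[tr], seed + k)
    oof[!tr] <- prob_of(mk, X[!tr, , drop = FALSE])
  }
  roc <- suppressMessages(pROC::roc(response = y, predictor = oof,
                                    levels = c("neg", "pos"),
                                    direction = "<"))
  cv_auc <- as.numeric(pROC::auc(roc))
  model <- fit_one(X, y, seed)
  scores <- pairs
  scores$prior <- as.integer(all_keys %in% prior_keys)
  scores$probability <- prob_of(model, .pair_features(pairs, prior_keys))
  scores$probability[match(tr_keys, all_keys)] <- oof
  structure(list(model = model, scores = scores, cv_auc = cv_auc,
                 cv_roc = data.frame(label = y, probability = oof),
                 classifier = classifier, seed = seed),
            class = "tf_classifier")
}

#' @export
print.tf_classifier <- function(x, ...) {
  cat(sprintf("tf_classifier (%s): CV AUC = %.3f; %d scored pairs (%d retained)\n",
              x$classifier, x$cv_auc, nrow(x$scores),
              sum(x$scores$retained)))
  invisible(x)
}

#' Scored edge list of the inferred TF network
#'
#' Retained pairs with classifier probability at or above `prob_min`.
#'
#' @param fit `tf_classifier`.
#' @param prob_min minimum probability, default 0.5.
#' @return data.frame `tf_a`, `tf_b`, `weight` (probability), `prior`.
#' @export
scored_edges <- function(fit, prob_min = 0.5) {
  s <- fit$scores
  s <- s[s$retained & s$probability >= prob_min, , drop = FALSE]
  data.frame(tf_a = s$tf_a, tf_b = s$tf_b, weight = s$probability,
             prior = s$prior, row.names = NULL)
}
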