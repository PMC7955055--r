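#' Soft-threshold selection for scale-free topology
#'
#' For each candidate power `beta`, builds the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` (Pearson on log2(FPKM+1) profiles),
#' computes connectivities `k_i = sum_{j != i} a_ij`, and scores the
#' scale-free fit as the squared correlation of `log10 p(k)` against
#' `log10 k` over connectivity bins, sign-penalised (a positive slope
#' flips the sign of R^2). The chosen power is the smallest candidate
#' whose signed R^2 reaches `r2_target`; if none does, the maximiser is
#' returned with a warning.
#'
#' @param expr numeric matrix, genes x conditions (log2(FPKM+1) scale).
#' @param powers candidate integer powers, default 1:20.
#' @param r2_target default 0.85.
#' @param n_bins connectivity bins for the fit, default 10.
#' @return list of class `soft_threshold`: `fit` data.frame (`power`,
#'   `r_squared`, `slope`, `mean_connectivity`) and `power` (chosen).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.85,
                                n_bins = 10) {
  if (ncol(expr) < 3) stop("need >= 3 conditions")
  if (nrow(expr) < 50) stop("need >= 50 genes")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit <- do.call(rbind, lapply(powers, function(beta) {
    a <- ac^beta
    k <- rowSums(a)
    sf <- .scale_free_fit(k, n_bins)
    data.frame(power = beta, r_squared = sf$r2, slope = sf$slope,
               mean_connectivity = mean(k))
  }))
  ok <- which(fit$r_squared >= r2_target)
  if (length(ok)) {
    power <- fit$power[ok[1]]
  } else {
    power <- fit$power[which.max(fit$r_squared)]
    warning(sprintf(
      "no power reaches R^2 >= %.2f; using maximiser beta = %d",
      r2_target, power))
  }
  structure(list(fit = fit, power = power), class = "soft_threshold")
}

# signed scale-free fit R^2 from a connectivity vector
.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kbar <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[keep]) ~ log10(kbar[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = -sign(slope) * r2, slope = unname(slope))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (diagonal excluded) and `k_i = sum_j a_ij`.
#' The diagonal is set to 1; dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with entries in [0, 1].
#' @return symmetric TOM matrix in [0, 1], diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0) || any(adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene
#'
#' First principal component of the row-standardised gene x condition
#' submatrix, sign-oriented to correlate positively with the module's
#' mean standardised profile. A single-gene module returns that gene's
#' standardised profile.
#'
#' @param expr genes x conditions matrix.
#' @param genes character vector of module member gene ids.
#' @return numeric vector over conditions.
#' @export
module_eigengene <- function(expr, genes) {
  if (length(genes) == 0) stop("empty module")
  x <- expr[genes, , drop = FALSE]
  x <- t(scale(t(x)))
  x[is.na(x)] <- 0
  if (nrow(x) == 1) return(drop(x))
  sv <- svd(x, nu = 0, nv = 1)
  eg <- sv$v[, 1] * sv$d[1] / sqrt(nrow(x))
  mp <- colMeans(x)
  if (sum(eg * mp) < 0) eg <- -eg
  stats::setNames(eg, colnames(expr))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, a height-based
#' dynamic cut of the tree, a minimum-size rule (small clusters go to
#' "grey"), and iterative merging of modules whose eigengenes have
#' dissimilarity `1 - cor` below `merge_threshold`.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param expr genes x conditions expression matrix (needed for
#'   eigengenes/merging; may be `NULL` to skip merging).
#' @param min_size minimum module size, default 30.
#' @param merge_threshold eigengene-dissimilarity merge threshold,
#'   default 0.35 (0 disables merging).
#' @param cut_height fraction of the dendrogram height range at which
#'   branches are cut, default 0.8 (a deep cut; the minimum-size rule and
#'   eigengene merging absorb any over-splitting).
#' @return list of class `module_assignment`: `module` (named character
#'   vector, "grey" = unassigned), `eigengenes` (matrix, module x
#'   condition), `min_size`, `merge_threshold`.
#' @export
detect_modules <- function(tom, expr = NULL, min_size = 30,
                           merge_threshold = 0.35, cut_height = 0.8) {
  genes <- rownames(tom)
  if (is.null(genes)) stop("tom needs gene dimnames")
  if (length(genes) < min_size) {
    warning("fewer genes than min_size; single grey module")
    return(structure(list(
      module = stats::setNames(rep("grey", length(genes)), genes),
      eigengenes = NULL, min_size = min_size,
      merge_threshold = merge_threshold), class = "module_assignment"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  hc$height <- cummax(hc$height)  # guard numerically tied merges
  h <- min(hc$height) + cut_height * diff(range(hc$height))
  cl <- stats::cutree(hc, h = h)
  # enforce min size
  sizes <- table(cl)
  grey_ids <- names(sizes)[sizes < min_size]
  lab <- ifelse(cl %in% as.integer(grey_ids), "grey",
                paste0("M", match(cl, sort(unique(
                  cl[!cl %in% as.integer(grey_ids)])))))
  names(lab) <- genes
  out <- structure(list(module = lab, eigengenes = NULL,
                        min_size = min_size,
                        merge_threshold = merge_threshold),
                   class = "module_assignment")
  if (!is.null(expr)) out <- .merge_modules(out, expr, merge_threshold)
  out
}

# iterative closest-pair merging on eigengene dissimilarity
.merge_modules <- function(assign, expr, merge_threshold) {
  repeat {
    mods <- setdiff(unique(assign$module), "grey")
    if (length(mods) == 0) { assign$eigengenes <- NULL; return(assign) }
    eg <- t(sapply(mods, function(m)
      module_eigengene(expr, names(assign$module)[assign$module == m])))
    rownames(eg) <- mods
    if (length(mods) == 1 || merge_threshold <= 0) {
      assign$eigengenes <- eg
      return(assign)
    }
    d <- 1 - stats::cor(t(eg))
    diag(d) <- Inf
    if (min(d) >= merge_threshold) {
      assign$eigengenes <- eg
      return(assign)
    }
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    keep <- mods[min(ij)]; drop <- mods[max(ij)]
    assign$module[assign$module == drop] <- keep
    # relabel to consecutive ids, preserving order of appearance
    mods2 <- setdiff(unique(assign$module), "grey")
    relab <- stats::setNames(paste0("M", seq_along(mods2)), mods2)
    newlab <- ifelse(assign$module == "grey", "grey",
                     relab[assign$module])
    names(newlab) <- names(assign$module)
    assign$module <- newlab
  }
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$module)
  cat("module_assignment:", length(x$module), "genes\n")
  print(tab)
  invisible(x)
}

#' Fuzzy c-means decomposition of a module into temporal trend clusters
#'
#' Gene profiles are standardised to mean 0, sd 1 and clustered with
#' fuzzy c-means (fuzzifier `m`, tolerance 1e-6, up to 500 iterations).
#' Initial centres are the two most anti-correlated member profiles
#' (deterministic), so mirrored trends within a module separate into the
#' two clusters. Centroids are re-standardised on output.
#'
#' @param expr genes x conditions matrix.
#' @param genes module member gene ids (>= `n_clusters` members).
#' @param n_clusters number of trend clusters, default 2.
#' @param m fuzzifier, default 2.
#' @return list of class `trend_clusters`: `centroids` (cluster x
#'   condition, standardised), `membership` (gene x cluster, rows sum to
#'   1), `excluded` (zero-variance genes dropped).
#' @export
fuzzy_trends <- function(expr, genes, n_clusters = 2, m = 2) {
  if (length(genes) < n_clusters)
    stop("module smaller than the cluster count")
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  excluded <- genes[sds == 0]
  if (length(excluded)) {
    warning(sprintf("excluding %d zero-variance profile(s)",
                    length(excluded)))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < n_clusters) stop("too few non-constant profiles")
  xs <- t(scale(t(x)))
  # deterministic init: the most mutually anti-correlated profiles
  cc <- stats::cor(t(xs))
  seedpair <- which(cc == min(cc), arr.ind = TRUE)[1, ]
  init_idx <- unique(c(seedpair, seq_len(nrow(xs))))[seq_len(n_clusters)]
  init <- xs[init_idx, , drop = FALSE]
  rownames(init) <- NULL
  cm <- .with_seed(0L, function()
    e1071::cmeans(xs, centers = init, m = m, iter.max = 500,
                  method = "cmeans"))
  cent <- t(apply(cm$centers, 1, function(z) (z - mean(z)) / stats::sd(z)))
  rownames(cent) <- paste0("trend", seq_len(n_clusters))
  mem <- cm$membership
  dimnames(mem) <- list(rownames(xs), rownames(cent))
  structure(list(centroids = cent, membership = mem, excluded = excluded),
            class = "trend_clusters")
}
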