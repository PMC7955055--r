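#' ARACNE-style mutual-information network with DPI pruning
#'
#' Pairwise plug-in mutual information (equal-frequency bins, same
#' estimator as [mi_score()] but un-normalised, in nats) over a set of
#' genes, pruned by the data-processing inequality: in every triangle
#' (i, j, k) the edge (i, j) is removed when
#' `MI(i,j) < min(MI(i,k), MI(j,k)) * (1 - dpi_tolerance)`, flagging it
#' as likely indirect. Constant profiles are dropped with a warning.
#'
#' @param expr genes x observations matrix (>= 3 genes, >= 3
#'   observations). MI on very few observations is high-variance; larger
#'   sample sizes are recommended.
#' @param mi_bins bins for the MI estimator, default 3.
#' @param dpi_tolerance in [0, 1), default 0.05.
#' @return data.frame `tf_a < tf_b`, `mi`, `removed` (DPI flag); the
#'   surviving network is the subset with `!removed`.
#' @export
aracne_network <- function(expr, mi_bins = 3, dpi_tolerance = 0.05) {
  if (dpi_tolerance < 0 || dpi_tolerance >= 1)
    stop("dpi_tolerance must be in [0, 1)")
  if (nrow(expr) < 3) stop("need >= 3 genes")
  if (ncol(expr) < 3) stop("need >= 3 observations")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant profile(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  n <- length(genes)
  bins <- t(apply(expr, 1, .ef_bins, n_bins = mi_bins))
  M <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ha <- .entropy(bins[i, ]); hb <- .entropy(bins[j, ])
    pj <- table(bins[i, ], bins[j, ]) / ncol(bins)
    hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
    M[i, j] <- M[j, i] <- max(0, ha + hb - hj)
  }
  dpi_prune(M, dpi_tolerance)
}

#' Data-processing-inequality pruning of a mutual-information matrix
#'
#' In every triangle (i, j, k) the edge (i, j) is flagged as indirect
#' when `MI(i,j) < min(MI(i,k), MI(j,k)) * (1 - dpi_tolerance)`. An edge
#' that is strictly the largest in each of its triangles is never
#' removed; with fewer than three nodes the rule is a no-op.
#'
#' @param mi symmetric nonnegative MI matrix with dimnames.
#' @param dpi_tolerance in [0, 1), default 0.05.
#' @return data.frame `tf_a < tf_b`, `mi`, `removed`.
#' @export
dpi_prune <- function(mi, dpi_tolerance = 0.05) {
  if (dpi_tolerance < 0 || dpi_tolerance >= 1)
    stop("dpi_tolerance must be in [0, 1)")
  if (!isSymmetric(unname(mi), tol = 1e-10)) stop("mi must be symmetric")
  genes <- rownames(mi)
  n <- nrow(mi)
  removed <- matrix(FALSE, n, n)
  if (n >= 3) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (mi[i, j] < min(mi[i, k], mi[j, k]) * (1 - dpi_tolerance)) {
        removed[i, j] <- removed[j, i] <- TRUE
        break
      }
    }
  }
  idx <- which(upper.tri(mi), arr.ind = TRUE)
  data.frame(tf_a = genes[idx[, 1]], tf_b = genes[idx[, 2]],
             mi = mi[idx], removed = removed[idx], row.names = NULL)
}

#' Directed GRN inference by per-target tree-ensemble regression
#'
#' For each target gene, a random-forest regression of the (unit
#' variance scaled) target profile on all candidate regulators other
#' than itself; the edge weight of regulator -> target is the
#' variance-reduction importance summed over trees, divided by the tree
#' count. All edges are ranked globally and the top `retain_fraction`
#' retained (`ceiling(retain_fraction * n_edges)` edges).
#'
#' @param expr genes x observations matrix (>= 5 observations).
#' @param regulators candidate regulator gene ids (>= 2, subset of
#'   rownames).
#' @param targets target gene ids, default all genes in `expr`.
#' @param n_trees default 500.
#' @param retain_fraction in (0, 1], default 0.25.
#' @param seed integer seed.
#' @return list of class `directed_grn`: `edges` (data.frame `regulator`,
#'   `target`, `weight`, `retained`), `nodes` (data.frame `node`,
#'   `in_degree`, `out_degree`, `degree` over retained edges).
#' @export
genie3_grn <- function(expr, regulators, targets = rownames(expr),
                       n_trees = 500, retain_fraction = 0.25, seed = 1) {
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must be in (0, 1]")
  if (length(regulators) < 2) stop("need >= 2 candidate regulators")
  if (ncol(expr) < 5) stop("need >= 5 observations")
  if (!all(regulators %in% rownames(expr)) ||
      !all(targets %in% rownames(expr)))
    stop("regulators/targets missing from expr")
  edges <- .with_seed(seed, function() {
    res <- list()
    for (tgt in targets) {
      regs <- setdiff(regulators, tgt)
      if (length(regs) < 1) next
      y <- expr[tgt, ]
      if (stats::sd(y) == 0) next
      y <- as.numeric(scale(y))
      X <- t(expr[regs, , drop = FALSE])
      if (length(regs) == 1) {
        # single-candidate degenerate case: weight by squared correlation
        res[[tgt]] <- data.frame(regulator = regs, target = tgt,
                                 weight = stats::cor(X[, 1], y)^2)
        next
      }
      rf <- randomForest::randomForest(
        X, y, ntree = n_trees, mtry = max(1, floor(sqrt(length(regs)))),
        importance = FALSE)
      imp <- rf$importance[, "IncNodePurity"] / n_trees
      res[[tgt]] <- data.frame(regulator = regs, target = tgt,
                               weight = unname(imp))
    }
    do.call(rbind, res)
  })
  if (is.null(edges)) stop("no scorable target")
  rownames(edges) <- NULL
  ord <- order(-edges$weight, edges$regulator, edges$target)
  n_keep <- ceiling(retain_fraction * nrow(edges))
  edges$retained <- FALSE
  edges$retained[ord[seq_len(n_keep)]] <- TRUE
  kept <- edges[edges$retained, , drop = FALSE]
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  node_stats <- data.frame(
    node = nodes,
    in_degree = as.integer(table(factor(kept$target, levels = nodes))),
    out_degree = as.integer(table(factor(kept$regulator,
                                         levels = nodes))))
  node_stats$degree <- node_stats$in_degree + node_stats$out_degree
  structure(list(edges = edges, nodes = node_stats),
            class = "directed_grn")
}

#' @export
print.directed_grn <- function(x, ...) {
  cat(sprintf("directed_grn: %d nodes, %d/%d edges retained\n",
              nrow(x$nodes), sum(x$edges$retained), nrow(x$edges)))
  invisible(x)
}

#' Rank hub genes of a directed GRN
#'
#' Nodes sorted by total degree (in + out) over retained edges, ties by
#' out-degree then node id.
#'
#' @param grn `directed_grn`.
#' @return data.frame of node statistics in hub order.
#' @export
rank_hubs <- function(grn) {
  stopifnot(inherits(grn, "directed_grn"))
  ns <- grn$nodes
  ns[order(-ns$degree, -ns$out_degree, ns$node), , drop = FALSE]
}

#' Static topology statistics of an undirected network
#'
#' Node/edge counts, density, connected components, per-component
#' characteristic path length and diameter (edge weights ignored for
#' paths), average neighbour count and the degree distribution.
#'
#' @param edges data.frame with columns `tf_a`, `tf_b` (weights, if
#'   present, are ignored for path statistics).
#' @param nodes optional vector of node ids, to include isolated nodes
#'   (required when `edges` is empty).
#' @return list `n_nodes`, `n_edges`, `density`, `n_components`,
#'   `characteristic_path_length` (mean over connected pairs),
#'   `diameter`, `average_neighbors`, `degree_distribution`.
#' @export
static_network_stats <- function(edges, nodes = NULL) {
  if (nrow(edges) == 0 && is.null(nodes)) stop("empty graph")
  g <- igraph::graph_from_data_frame(
    edges[, c("tf_a", "tf_b")], directed = FALSE,
    vertices = if (is.null(nodes)) NULL else
      unique(c(nodes, edges$tf_a, edges$tf_b)))
  deg <- igraph::degree(g)
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       density = igraph::edge_density(g),
       n_components = igraph::components(g)$no,
       characteristic_path_length =
         igraph::mean_distance(g, unconnected = TRUE),
       diameter = igraph::diameter(g, weights = NA),
       average_neighbors = mean(deg),
       degree_distribution = table(deg))
}
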