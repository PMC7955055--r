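# internal weighted-adjacency representation of an undirected edge list
.edge_adjacency <- function(edges) {
  nodes <- sort(unique(c(edges$tf_a, edges$tf_b)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w <- if ("weight" %in% names(edges)) edges$weight else
    rep(1, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    A[edges$tf_a[i], edges$tf_b[i]] <- w[i]
    A[edges$tf_b[i], edges$tf_a[i]] <- w[i]
  }
  A
}

.coh_value <- function(w_in, w_bound, penalty, size) {
  denom <- w_in + w_bound + penalty * size
  ifelse(denom == 0, 0, w_in / denom)
}

# Greedy local search for a cohesive set, started from V0: at each step
# the single vertex addition or removal that most increases f(V) is
# applied (ties broken by lexicographic vertex id). Incremental
# w_in / w_bound bookkeeping keeps each step O(n |V|). Returns the
# sorted member vector with the final cohesiveness in attribute "f".
.grow_cluster <- function(A, deg, V0, penalty) {
  nodes <- colnames(A)
  V <- V0
  inside <- nodes %in% V
  w_in <- sum(A[inside, inside, drop = FALSE]) / 2
  w_bound <- sum(A[inside, !inside, drop = FALSE])
  f <- .coh_value(w_in, w_bound, penalty, length(V))
  repeat {
    s <- colSums(A[V, , drop = FALSE])  # weight from V to each vertex
    inV <- nodes %in% V
    f_add <- ifelse(!inV & s > 0,
                    .coh_value(w_in + s, w_bound + deg - 2 * s, penalty,
                               length(V) + 1), -Inf)
    f_rem <- if (length(V) > 1)
      ifelse(inV, .coh_value(w_in - s, w_bound - deg + 2 * s, penalty,
                             length(V) - 1), -Inf)
    else rep(-Inf, length(nodes))
    best <- pmax(f_add, f_rem)
    if (max(best) <= f + 1e-12) break
    v <- nodes[best > max(best) - 1e-15][1]
    if (!inV[match(v, nodes)]) {
      w_in <- w_in + s[v]; w_bound <- w_bound + deg[v] - 2 * s[v]
      V <- c(V, v)
    } else {
      w_in <- w_in - s[v]; w_bound <- w_bound - deg[v] + 2 * s[v]
      V <- setdiff(V, v)
    }
    f <- .coh_value(w_in, w_bound, penalty, length(V))
  }
  out <- sort(V)
  attr(out, "f") <- f
  out
}

# cohesiveness f(V) = w_in / (w_in + w_bound + penalty * |V|)
.cohesiveness <- function(A, members, penalty) {
  inside <- colnames(A) %in% members
  w_in <- sum(A[inside, inside, drop = FALSE]) / 2
  w_bound <- sum(A[inside, !inside, drop = FALSE])
  denom <- w_in + w_bound + penalty * sum(inside)
  if (denom == 0) return(0)
  w_in / denom
}

#' Cohesive overlapping cluster detection (ClusterONE-style)
#'
#' Greedy seeded growth of cohesive groups on a weighted undirected
#' graph. Cohesiveness of a vertex set V is
#' `f(V) = w_in / (w_in + w_bound + penalty * |V|)` where `w_in` is the
#' total internal edge weight and `w_bound` the total weight crossing the
#' boundary. Seeds are taken in decreasing weighted-degree order over
#' vertices not yet in any cluster; at each step the single addition or
#' removal that most increases f(V) is applied (ties broken by
#' lexicographic vertex id) until no move improves. Grown candidates with
#' pairwise overlap `|A n B|^2 / (|A| |B|) >= overlap_threshold` are
#' merged, and clusters below `min_size` or internal weighted density
#' below `min_density` are discarded.
#'
#' @param edges data.frame `tf_a`, `tf_b`, optional `weight` in [0, 1].
#' @param penalty cohesiveness penalty, default 2.
#' @param min_size minimum cluster size, default 3.
#' @param min_density minimum internal density `2 w_in / (|V| (|V|-1))`,
#'   default 0.3.
#' @param overlap_threshold merge threshold omega in (0, 1], default 0.8.
#' @return list of class `cluster_set`: `clusters` (list of member
#'   vectors), `cohesiveness`, `density`, and `params`.
#' @export
cluster_one <- function(edges, penalty = 2, min_size = 3,
                        min_density = 0.3, overlap_threshold = 0.8) {
  if (penalty < 0) stop("penalty must be >= 0")
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop("overlap_threshold must be in (0, 1]")
  if (nrow(edges) == 0)
    return(structure(list(clusters = list(), cohesiveness = numeric(0),
                          density = numeric(0),
                          params = list(penalty = penalty,
                                        min_size = min_size,
                                        min_density = min_density,
                                        overlap_threshold =
                                          overlap_threshold)),
                     class = "cluster_set"))
  A <- .edge_adjacency(edges)
  nodes <- colnames(A)
  deg <- rowSums(A)
  # every vertex seeds a growth (duplicates collapse afterwards)
  candidates <- unique(lapply(nodes[order(-deg, nodes)], function(v)
    .grow_cluster(A, deg, v, penalty)))
  # beneficial-union pass: a refined union of two candidates replaces
  # neither but joins the pool when it is more cohesive than both
  for (pass in 1:3) {
    fs <- vapply(candidates, function(cl) attr(cl, "f"), numeric(1))
    n_cand <- length(candidates)
    new_cand <- list()
    for (i in seq_len(n_cand - 1)) for (j in seq(i + 1, n_cand)) {
      u <- .grow_cluster(A, deg,
                         union(candidates[[i]], candidates[[j]]), penalty)
      if (attr(u, "f") > max(fs[i], fs[j]) + 1e-12)
        new_cand[[length(new_cand) + 1]] <- u
    }
    key <- function(cl) paste(cl, collapse = "|")
    have <- vapply(candidates, key, character(1))
    new_cand <- new_cand[!duplicated(vapply(new_cand, key, character(1)))]
    new_cand <- new_cand[!vapply(new_cand, key, character(1)) %in% have]
    if (length(new_cand) == 0) break
    candidates <- c(candidates, new_cand)
  }
  clusters <- .merge_overlapping(unique(lapply(candidates, as.vector)),
                                 overlap_threshold)
  coh <- vapply(clusters, .cohesiveness, numeric(1), A = A,
                penalty = penalty)
  dens <- vapply(clusters, function(V) {
    if (length(V) < 2) return(0)
    inside <- colnames(A) %in% V
    sum(A[inside, inside]) / (length(V) * (length(V) - 1))
  }, numeric(1))
  keep <- lengths(clusters) >= min_size & dens >= min_density
  structure(list(clusters = clusters[keep], cohesiveness = coh[keep],
                 density = dens[keep],
                 params = list(penalty = penalty, min_size = min_size,
                               min_density = min_density,
                               overlap_threshold = overlap_threshold)),
            class = "cluster_set")
}

# merge vertex sets whose overlap score reaches omega, to a fixpoint
.merge_overlapping <- function(sets, omega) {
  repeat {
    if (length(sets) < 2) return(sets)
    merged <- FALSE
    for (i in seq_len(length(sets) - 1)) {
      for (j in seq(i + 1, length(sets))) {
        ov <- length(intersect(sets[[i]], sets[[j]]))^2 /
          (length(sets[[i]]) * length(sets[[j]]))
        if (ov >= omega) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          sets <- sets[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(unique(sets))
  }
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (sizes %s)\n", length(x$clusters),
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' Hypergeometric term enrichment of a gene cluster
#'
#' One-tailed upper hypergeometric p per term, BH-adjusted across terms.
#' Terms with zero overlap with the universe are skipped.
#'
#' @param members cluster gene ids (subset of the universe).
#' @param annotations `annotation_collection` (or a named list of gene
#'   sets).
#' @param universe gene universe; defaults to the collection's.
#' @return data.frame `term`, `overlap`, `term_size`, `p`, `padj`.
#' @export
hypergeometric_enrichment <- function(members, annotations,
                                      universe = NULL) {
  sets <- if (inherits(annotations, "annotation_collection"))
    annotations$sets else annotations
  if (is.null(universe)) universe <- annotations$universe
  members <- intersect(members, universe)
  N <- length(universe)
  res <- lapply(names(sets), function(term) {
    m <- length(intersect(sets[[term]], universe))
    if (m == 0) return(NULL)
    k <- length(intersect(members, sets[[term]]))
    p <- stats::phyper(k - 1, m, N - m, length(members),
                       lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = m, p = p)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), p = numeric(0),
                      padj = numeric(0)))
  res$padj <- bh_adjust(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Random-network significance null for cluster enrichment
#'
#' Draws `n_draws` sets of random clusters size-matched to the observed
#' ones from the TF pool, runs the same hypergeometric enrichment on
#' each, and records the best adjusted p per random cluster. Reports the
#' frequency of draws per significance band and, when observed best-p
#' values are supplied, a one-sided comparison of the observed
#' distribution against the null.
#'
#' @param tf_pool genes from which random clusters are drawn.
#' @param cluster_sizes observed cluster sizes (each <= pool size).
#' @param annotations `annotation_collection`.
#' @param n_draws default 100.
#' @param seed integer seed.
#' @param bands significance band edges for the frequency report.
#' @param observed_best_p optional vector of observed per-cluster best
#'   adjusted p.
#' @param universe enrichment universe, defaults to the collection's.
#' @return list of class `null_distribution`: `best_padj` (draws x
#'   clusters matrix), `band_freq`, `frac_sig` (fraction of random
#'   clusters with best padj < 0.05), `seed`, and when observed values
#'   are given, `observed_frac_sig` and `wilcox_p` (one-sided: observed
#'   smaller).
#' @export
random_network_null <- function(tf_pool, cluster_sizes, annotations,
                                n_draws = 100, seed = 1,
                                bands = c(0, 1e-10, 1e-5, 1e-3, 0.01,
                                          0.05, 1),
                                observed_best_p = NULL, universe = NULL) {
  if (max(cluster_sizes) > length(tf_pool))
    stop("pool smaller than the largest cluster")
  best <- .with_seed(seed, function() {
    t(vapply(seq_len(n_draws), function(d) {
      vapply(cluster_sizes, function(sz) {
        cl <- sample(tf_pool, sz)
        e <- hypergeometric_enrichment(cl, annotations, universe)
        if (nrow(e) == 0) 1 else min(e$padj)
      }, numeric(1))
    }, numeric(length(cluster_sizes))))
  })
  if (length(cluster_sizes) == 1) best <- matrix(best, ncol = 1)
  band_freq <- table(cut(as.vector(best), bands, include.lowest = TRUE)) /
    length(best)
  out <- list(best_padj = best, band_freq = band_freq,
              frac_sig = mean(best < 0.05), n_draws = n_draws,
              seed = seed)
  if (!is.null(observed_best_p)) {
    out$observed_frac_sig <- mean(observed_best_p < 0.05)
    out$wilcox_p <- stats::wilcox.test(observed_best_p, as.vector(best),
                                       alternative = "less",
                                       exact = FALSE)$p.value
  }
  structure(out, class = "null_distribution")
}

#' Two-tailed hypergeometric pathway-overlap test
#'
#' Tests whether two DE gene lists overlap on a pathway more than chance:
#' with `m` pathway genes, `nA` of them in list A, `nB` in list B and `k`
#' in both, the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(m, nA, nB)` is computed, doubled and capped at 1
#' for the two-tailed report. Both the raw upper tail and the doubled
#' value are returned, with `-log10` of each.
#'
#' @param de_a,de_b DE gene sets (character vectors).
#' @param pathway pathway gene set.
#' @param pathway_size pathway size `m`; defaults to `length(pathway)`
#'   (the database value may exceed the genes observed in the data).
#' @return list `m`, `n_a`, `n_b`, `k`, `p_upper`, `p_two_tailed`,
#'   `neg_log10_p_upper`, `neg_log10_p_two_tailed`.
#' @export
pathway_overlap_test <- function(de_a, de_b, pathway,
                                 pathway_size = length(pathway)) {
  nA <- length(intersect(de_a, pathway))
  nB <- length(intersect(de_b, pathway))
  k <- length(intersect(intersect(de_a, de_b), pathway))
  m <- pathway_size
  if (k > min(nA, nB)) stop("k cannot exceed min(nA, nB)")
  if (m < max(nA, nB)) stop("pathway size smaller than a DE overlap")
  p_upper <- if (k == 0) 1 else
    stats::phyper(k - 1, nA, m - nA, nB, lower.tail = FALSE)
  p_two <- min(1, 2 * p_upper)
  list(m = m, n_a = nA, n_b = nB, k = k, p_upper = p_upper,
       p_two_tailed = p_two, neg_log10_p_upper = -log10(p_upper),
       neg_log10_p_two_tailed = -log10(p_two))
}

#' Power-law check of a degree distribution
#'
#' Log-log linear regression of the binned degree frequency. Returns the
#' slope (the negated exponent estimate) and fit R^2; degenerate inputs
#' (all degrees equal) report missing values.
#'
#' @param degrees integer degree vector (>= 20 nodes), or a data.frame of
#'   edges (`tf_a`, `tf_b`) from which degrees are counted.
#' @param n_bins number of logarithmic bins, default 10.
#' @return list `exponent` (slope), `r_squared`; both `NA` when
#'   undefined.
#' @export
degree_powerlaw_check <- function(degrees, n_bins = 10) {
  if (is.data.frame(degrees))
    degrees <- as.vector(table(c(degrees$tf_a, degrees$tf_b)))
  if (length(degrees) < 20) stop("need >= 20 nodes")
  degrees <- degrees[degrees > 0]
  if (length(unique(degrees)) < 3)
    return(list(exponent = NA_real_, r_squared = NA_real_))
  br <- exp(seq(log(min(degrees)), log(max(degrees) + 1),
                length.out = n_bins + 1))
  bin <- cut(degrees, unique(br), include.lowest = TRUE)
  freq <- tapply(degrees, bin, length)
  dbar <- tapply(degrees, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3)
    return(list(exponent = NA_real_, r_squared = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(dbar[keep]))
  list(exponent = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}
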