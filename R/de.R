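#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_i = min_{j: p_j >= p_i} n p_j / rank_j`, clipped
#' to [0, 1]. Delegates to [stats::p.adjust()]; input validation and the
#' monotonicity contract are what this wrapper adds.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted FDR values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Method-of-moments NB dispersion from pseudo-counts, pooled across the
# two groups. Tagwise values are shrunk toward the pooled common
# dispersion with weight df / (df + prior_df): at 2-3 replicates the
# per-gene moments carry little information and the common value
# dominates, which keeps the exact test's tail calibrated.
.nb_dispersion <- function(a, b, mode, fixed = NULL, prior_df = 20) {
  if (mode == "fixed") {
    if (is.null(fixed) || fixed < 0) stop("fixed dispersion must be >= 0")
    return(rep(fixed, nrow(a)))
  }
  mom_one <- function(m) {
    if (ncol(m) < 2) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    phi <- (v - mu) / mu^2
    phi[!is.finite(phi)] <- NA
    pmax(phi, 0)
  }
  pa <- mom_one(a); pb <- mom_one(b)
  tag <- rowMeans(cbind(pa, pb), na.rm = TRUE)
  tag[is.nan(tag)] <- NA
  # pooled moment estimator of the common dispersion: solving
  # sum(v) = sum(mu) + phi * sum(mu^2) over all genes and both groups
  # is far more stable at 2-3 replicates than a per-gene median
  pool_num <- pool_den <- 0
  for (m in list(a, b)) {
    if (ncol(m) < 2) next
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    pool_num <- pool_num + sum(v - mu)
    pool_den <- pool_den + sum(mu^2)
  }
  common <- if (pool_den > 0) max(0, pool_num / pool_den) else 0.1
  if (mode == "common") return(rep(common, nrow(a)))
  tag[is.na(tag)] <- common
  df <- max(0, ncol(a) - 1) + max(0, ncol(b) - 1)
  w <- df / (df + prior_df)
  w * tag + (1 - w) * common
}

# Two-sided exact p for group-A sum given the total, under NB (or Poisson
# when phi == 0) with nA and nB samples per group. Probability-mass method:
# sum the conditional masses no larger than that of the observed split.
.nb_exact_p <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  # restrict the support window for very large totals
  if (s > 20000) {
    center <- s * nA / (nA + nB)
    halfw <- 20 * sqrt(s * max(1, 1 + phi * mu))
    ys <- max(0, floor(center - halfw)):min(s, ceiling(center + halfw))
    ys <- union(ys, sA)
  } else ys <- 0:s
  if (phi <= 0) {
    la <- stats::dpois(ys, nA * mu, log = TRUE)
    lb <- stats::dpois(s - ys, nB * mu, log = TRUE)
  } else {
    la <- stats::dnbinom(ys, mu = nA * mu, size = nA / phi, log = TRUE)
    lb <- stats::dnbinom(s - ys, mu = nB * mu, size = nB / phi, log = TRUE)
  }
  lp <- la + lb
  lobs <- lp[match(sA, ys)]
  tot <- sum(exp(lp - max(lp)))
  min(1, sum(exp(lp[lp <= lobs + 1e-8] - max(lp))) / tot)
}

#' Negative-binomial exact test between two sample groups
#'
#' Library sizes are equalised by scaling every sample's counts to the
#' geometric-mean library size (rounded pseudo-counts); the two-sided
#' p-value then comes from the exact conditional distribution of the
#' group-A sum given the total sum under a negative-binomial model with
#' the chosen dispersion. `dispersion -> 0` recovers the binomial exact
#' test of the A-sum given the total (Poisson limit). log2 fold-changes
#' use normalised group means with a 0.5 pseudo-count.
#'
#' @param counts_a,counts_b integer count matrices (genes x samples) with
#'   identical rownames.
#' @param dispersion_mode `"tagwise-moments"` (default; method-of-moments
#'   per gene, shrunk toward the pooled common dispersion with weight
#'   df/(df + 20)), `"common"`, or `"fixed"`.
#' @param dispersion value used when `dispersion_mode = "fixed"`.
#' @return data.frame with columns `gene`, `logFC`, `pvalue`. Genes with
#'   zero total count get `p = 1`, `logFC = 0`.
#' @export
nb_exact_test <- function(counts_a, counts_b,
                          dispersion_mode = c("tagwise-moments", "common",
                                              "fixed"),
                          dispersion = NULL) {
  dispersion_mode <- match.arg(dispersion_mode)
  if (!identical(rownames(counts_a), rownames(counts_b)))
    stop("count matrices must share rownames")
  if (dispersion_mode != "fixed" &&
      (ncol(counts_a) < 2 || ncol(counts_b) < 2))
    stop("need >= 2 samples per group (or a fixed dispersion)")
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  libs <- c(colSums(counts_a), colSums(counts_b))
  if (any(libs == 0)) stop("zero-library sample")
  ref <- exp(mean(log(libs)))
  pa <- round(sweep(counts_a, 2, ref / colSums(counts_a), "*"))
  pb <- round(sweep(counts_b, 2, ref / colSums(counts_b), "*"))
  phi <- .nb_dispersion(pa, pb, dispersion_mode, dispersion)
  nA <- ncol(pa); nB <- ncol(pb)
  sA <- rowSums(pa); sB <- rowSums(pb)
  p <- vapply(seq_len(nrow(pa)), function(i)
    .nb_exact_p(sA[i], sB[i], nA, nB, phi[i]), numeric(1))
  lfc <- log2((sA / nA + 0.5) / (sB / nB + 0.5))
  lfc[sA + sB == 0] <- 0
  data.frame(gene = rownames(counts_a), logFC = lfc, pvalue = p,
             row.names = NULL)
}

#' Differential expression over adjacent timepoints
#'
#' Runs [nb_exact_test()] for every adjacent pair of timepoints in a count
#' `expr_set`, applies BH adjustment per contrast, and flags DE genes.
#'
#' @param x `expr_set` of counts.
#' @param fdr_max FDR threshold, default 0.01.
#' @param fc_min fold-change threshold; DE requires FC > `fc_min` or
#'   FC < 1/`fc_min`. Default 2.
#' @param ... passed to [nb_exact_test()].
#' @return data.frame (class `deg_table`) with columns `gene`, `contrast`,
#'   `logFC`, `pvalue`, `FDR`, `de_flag`; thresholds kept as attributes.
#' @export
de_adjacent <- function(x, fdr_max = 0.01, fc_min = 2, ...) {
  stopifnot(inherits(x, "expr_set"))
  if (x$unit != "counts") stop("de_adjacent expects count data")
  tps <- levels(x$sample_meta$timepoint)
  if (length(tps) < 2) stop("need >= 2 timepoints")
  res <- list()
  for (i in seq_len(length(tps) - 1)) {
    a <- x$sample_meta$sample[x$sample_meta$timepoint == tps[i + 1]]
    b <- x$sample_meta$sample[x$sample_meta$timepoint == tps[i]]
    tab <- nb_exact_test(x$values[, a, drop = FALSE],
                         x$values[, b, drop = FALSE], ...)
    tab$contrast <- paste(tps[i], tps[i + 1], sep = "-")
    tab$FDR <- bh_adjust(tab$pvalue)
    res[[i]] <- tab
  }
  out <- do.call(rbind, res)[, c("gene", "contrast", "logFC", "pvalue", "FDR")]
  out$de_flag <- call_degs(out, fdr_max = fdr_max, fc_min = fc_min)
  attr(out, "fdr_max") <- fdr_max
  attr(out, "fc_min") <- fc_min
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' DE requires FDR < `fdr_max` and fold-change > `fc_min` or < 1/`fc_min`.
#'
#' @param tab data.frame with columns `FDR` and `logFC`.
#' @param fdr_max,fc_min thresholds (defaults 0.01 and 2).
#' @return logical DE flags, one per row of `tab`.
#' @export
call_degs <- function(tab, fdr_max = 0.01, fc_min = 2) {
  stopifnot(all(c("FDR", "logFC") %in% names(tab)))
  tab$FDR < fdr_max & abs(tab$logFC) > log2(fc_min)
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table: %d genes x %d contrasts (FDR < %g, FC > %g)\n",
              length(unique(x$gene)), length(unique(x$contrast)),
              attr(x, "fdr_max"), attr(x, "fc_min")))
  print(tapply(x$de_flag, x$contrast, sum))
  invisible(x)
}

#' Partition DE genes into periodic and continuous sets
#'
#' Periodically expressed genes (PEGs) change between few adjacent
#' timepoints; continuously expressed genes (CEGs) keep changing. Two
#' rules are exposed, because counting contrasts and counting touched
#' timepoints give different splits:
#' \describe{
#'   \item{`"contrasts"`}{(default) DE in exactly 1 adjacent contrast ->
#'     PEG; DE in >= 2 contrasts -> CEG.}
#'   \item{`"timepoints"`}{DE contrasts touching exactly 2 distinct
#'     timepoints -> PEG; touching >= 3 -> CEG. Differs from
#'     `"contrasts"` only for genes whose multiple DE contrasts overlap.}
#' }
#'
#' @param deg `deg_table` from [de_adjacent()].
#' @param rule `"contrasts"` or `"timepoints"`.
#' @return list with `peg`, `ceg` (character vectors), `rule`, and
#'   `n_contrasts_de` (named integer vector over DE genes).
#' @export
partition_peg_ceg <- function(deg, rule = c("contrasts", "timepoints")) {
  rule <- match.arg(rule)
  de <- deg[deg$de_flag, , drop = FALSE]
  if (nrow(de) == 0)
    return(list(peg = character(0), ceg = character(0), rule = rule,
                n_contrasts_de = integer(0)))
  ncon <- tapply(de$contrast, de$gene, function(z) length(unique(z)))
  if (rule == "contrasts") {
    peg <- names(ncon)[ncon == 1]
    ceg <- names(ncon)[ncon >= 2]
  } else {
    ntp <- tapply(de$contrast, de$gene, function(z)
      length(unique(unlist(strsplit(unique(z), "-", fixed = TRUE)))))
    peg <- names(ntp)[ntp == 2]
    ceg <- names(ntp)[ntp >= 3]
  }
  list(peg = peg, ceg = ceg, rule = rule,
       n_contrasts_de = ncon[order(names(ncon))])
}
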