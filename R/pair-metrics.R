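#' Jaccard co-detection score
#'
#' Number of timepoints at which both genes are detected divided by the
#' number at which at least one is; detection means FPKM >= `detect_min`.
#' Returns 0 when neither gene is detected anywhere.
#'
#' @param x_a,x_b FPKM vectors over timepoints, equal length >= 1.
#' @param detect_min detection threshold, default 1.
#' @return real in [0, 1].
#' @export
jaccard_score <- function(x_a, x_b, detect_min = 1) {
  if (length(x_a) != length(x_b)) stop("length mismatch")
  da <- x_a >= detect_min; db <- x_b >= detect_min
  u <- sum(da | db)
  if (u == 0) return(0)
  sum(da & db) / u
}

#' Pearson correlation of raw FPKM profiles
#'
#' @param x_a,x_b FPKM vectors, equal length >= 3, both non-constant.
#' @return Pearson r in [-1, 1]; `NA` for a constant vector (callers map
#'   this to 0.5 after rescaling to [0, 1]).
#' @export
pcc_score <- function(x_a, x_b) {
  if (length(x_a) != length(x_b)) stop("length mismatch")
  if (length(x_a) < 3) stop("need length >= 3")
  if (stats::sd(x_a) == 0 || stats::sd(x_b) == 0) return(NA_real_)
  stats::cor(x_a, x_b)
}

# equal-frequency binning into n_bins by rank
.ef_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  ceiling(r * n_bins / length(x))
}

# plug-in entropy of a discrete vector, in nats
.entropy <- function(b) {
  p <- table(b) / length(b)
  -sum(p * log(p))
}

#' Normalised mutual information
#'
#' Plug-in mutual information on equal-frequency bins of each vector,
#' normalised by the smaller marginal entropy so the score lands in
#' [0, 1]; 0 when either marginal entropy is 0. With short vectors the
#' plug-in estimate is upward biased, which is accepted: the score is a
#' feature, not a calibrated statistic.
#'
#' @param x_a,x_b numeric vectors, equal length >= `n_bins`.
#' @param n_bins number of bins, default 3.
#' @return real in [0, 1].
#' @export
mi_score <- function(x_a, x_b, n_bins = 3) {
  if (length(x_a) != length(x_b)) stop("length mismatch")
  if (n_bins < 2) stop("need n_bins >= 2")
  if (length(x_a) < n_bins) stop("need length >= n_bins")
  ba <- .ef_bins(x_a, n_bins); bb <- .ef_bins(x_b, n_bins)
  ha <- .entropy(ba); hb <- .entropy(bb)
  if (ha == 0 || hb == 0) return(0)
  pj <- table(ba, bb) / length(ba)
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  mi <- ha + hb - hj
  min(1, max(0, mi / min(ha, hb)))
}

#' Bayes correlation of abundance profiles
#'
#' Posterior-moment correlation under a Dirichlet-multinomial model of
#' the timepoint proportions. Each profile gets a Dirichlet(`alpha`)
#' prior; the correlation of the posterior-mean proportion vectors is
#' computed with the average posterior variance added to each empirical
#' variance, which shrinks the score toward 0 when total abundance is
#' low and recovers the plain proportion correlation as counts grow.
#' The result is rescaled to [0, 1] as (r + 1)/2; an all-zero pair gives
#' the uninformative 0.5.
#'
#' @param x_a,x_b nonnegative abundance vectors, equal length >= 2.
#' @param alpha Dirichlet pseudo-count per timepoint, default 1.
#' @return real in [0, 1].
#' @export
bayes_cor <- function(x_a, x_b, alpha = 1) {
  if (length(x_a) != length(x_b)) stop("length mismatch")
  if (length(x_a) < 2) stop("need length >= 2")
  if (any(x_a < 0) || any(x_b < 0)) stop("negative abundances")
  post <- function(x) {
    a <- x + alpha
    S <- sum(a)
    m <- a / S
    v <- a * (S - a) / (S^2 * (S + 1))  # posterior var of each proportion
    list(m = m, vbar = mean(v))
  }
  pa <- post(x_a); pb <- post(x_b)
  n <- length(x_a)
  cv <- sum((pa$m - mean(pa$m)) * (pb$m - mean(pb$m))) / (n - 1)
  sa <- sqrt(stats::var(pa$m) + pa$vbar)
  sb <- sqrt(stats::var(pb$m) + pb$vbar)
  if (sa == 0 || sb == 0) return(0.5)
  (cv / (sa * sb) + 1) / 2
}

#' Apex (shared peak-time) score
#'
#' 1 iff both genes peak at the same timepoint; argmax ties resolve to
#' the earliest index.
#'
#' @param x_a,x_b numeric vectors, equal length >= 1.
#' @return 0 or 1.
#' @export
apex_score <- function(x_a, x_b) {
  if (length(x_a) != length(x_b)) stop("length mismatch")
  as.integer(which.max(x_a) == which.max(x_b))
}

#' Score all TF pairs with the five co-expression metrics
#'
#' Every unordered pair from `tf_list` is scored (Jaccard, PCC, MI,
#' Bayes, Apex) on the timepoint-averaged FPKM matrix. A pair is retained
#' when the maximum over the four continuous [0, 1] features (jaccard,
#' rescaled pcc = (r+1)/2, mi, bayes) reaches `threshold`; the full table
#' is returned with the flag so that higher thresholds always select a
#' subset.
#'
#' @param expr genes x timepoints FPKM matrix.
#' @param tf_list TF gene ids, all present in `expr`, length >= 2.
#' @param threshold retain threshold, default 0.75 (0.85 is the stricter
#'   alternative).
#' @param detect_min Jaccard detection threshold, default 1.
#' @param mi_bins MI bins, default 3.
#' @return data.frame of class `pair_table`: `tf_a < tf_b`, `jaccard`,
#'   `pcc`, `pcc01`, `mi`, `bayes`, `apex`, `retained`.
#' @export
build_pair_table <- function(expr, tf_list, threshold = 0.75,
                             detect_min = 1, mi_bins = 3) {
  tf_list <- sort(unique(tf_list))
  if (length(tf_list) < 2) stop("need >= 2 TFs")
  if (!all(tf_list %in% rownames(expr)))
    stop("TFs missing from the expression matrix")
  cmb <- utils::combn(tf_list, 2)
  n <- ncol(cmb)
  jac <- pcc <- mi <- bay <- apx <- numeric(n)
  for (i in seq_len(n)) {
    a <- expr[cmb[1, i], ]; b <- expr[cmb[2, i], ]
    jac[i] <- jaccard_score(a, b, detect_min)
    pcc[i] <- pcc_score(a, b)
    mi[i] <- mi_score(a, b, mi_bins)
    bay[i] <- bayes_cor(a, b)
    apx[i] <- apex_score(a, b)
  }
  pcc01 <- ifelse(is.na(pcc), 0.5, (pcc + 1) / 2)
  out <- data.frame(tf_a = cmb[1, ], tf_b = cmb[2, ], jaccard = jac,
                    pcc = pcc, pcc01 = pcc01, mi = mi, bayes = bay,
                    apex = apx)
  out$retained <- pmax(out$jaccard, out$pcc01, out$mi, out$bayes) >=
    threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("pair_table", "data.frame")
  out
}
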