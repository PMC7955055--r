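#' Expression set container
#'
#' Light-weight container for a genes x samples abundance matrix together
#' with the metadata the pipeline needs: the measurement unit, per-sample
#' timepoint/replicate labels and (for count data) gene lengths.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param unit one of `"counts"`, `"fpkm"` or `"log2fpkm1"`.
#' @param sample_meta data.frame with columns `sample`, `timepoint`,
#'   `replicate`; one row per column of `values`. `timepoint` is coerced to
#'   a factor whose level order defines developmental time.
#' @param gene_lengths named numeric vector of transcript lengths in bp,
#'   one entry per gene. Required when `unit == "counts"`.
#'
#' @return An object of class `expr_set`: a list with elements `values`,
#'   `unit`, `sample_meta`, `gene_lengths`.
#' @export
expr_set <- function(values, unit = c("counts", "fpkm", "log2fpkm1"),
                     sample_meta, gene_lengths = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique")
  if (!is.data.frame(sample_meta) ||
      !all(c("sample", "timepoint", "replicate") %in% names(sample_meta)))
    stop("'sample_meta' needs columns sample, timepoint, replicate")
  if (!setequal(sample_meta$sample, colnames(values)))
    stop("sample_meta does not match the columns of 'values'")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (!is.factor(sample_meta$timepoint))
    sample_meta$timepoint <- factor(sample_meta$timepoint,
                                    levels = unique(sample_meta$timepoint))
  if (unit == "counts") {
    if (is.null(gene_lengths))
      stop("'gene_lengths' required for count data")
    if (!all(rownames(values) %in% names(gene_lengths)))
      stop("every gene needs a length")
    gene_lengths <- gene_lengths[rownames(values)]
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  }
  structure(list(values = values, unit = unit, sample_meta = sample_meta,
                 gene_lengths = gene_lengths),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tp <- table(x$sample_meta$timepoint)
  cat("timepoints:", paste(sprintf("%s(%d)", names(tp), tp), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Convert counts to FPKM
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' \eqn{FPKM_{gs} = 10^9 c_{gs} / (N_s L_g)} where \eqn{c_{gs}} is the read
#' count, \eqn{N_s} the library size (column sum) and \eqn{L_g} the
#' transcript length in bp.
#'
#' @param x `expr_set` with `unit == "counts"`.
#' @return `expr_set` with `unit == "fpkm"`.
#' @export
compute_fpkm <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$unit != "counts") stop("compute_fpkm expects count data")
  if (any(x$gene_lengths <= 0)) stop("zero-length gene")
  N <- colSums(x$values)
  if (any(N <= 0)) stop("zero-library sample")
  fpkm <- 1e9 * sweep(sweep(x$values, 2, N, "/"), 1, x$gene_lengths, "/")
  out <- x
  out$values <- fpkm
  out$unit <- "fpkm"
  out
}

#' Replicate concordance QC
#'
#' Pearson correlation between biological replicates of each timepoint,
#' computed on log2(FPKM + 1). Missing values are treated as 0 before the
#' transform. A replicate whose transformed vector is constant yields
#' `NA` correlations with a warning rather than an error.
#'
#' @param x `expr_set` with `unit == "fpkm"`.
#' @return named list (one element per timepoint) of replicate x replicate
#'   correlation matrices; timepoints with a single replicate give `NULL`.
#' @export
replicate_qc <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$unit != "fpkm") stop("replicate_qc expects FPKM data")
  v <- x$values
  v[is.na(v)] <- 0
  lv <- log2(v + 1)
  out <- list()
  for (tp in levels(x$sample_meta$timepoint)) {
    cols <- x$sample_meta$sample[x$sample_meta$timepoint == tp]
    if (length(cols) < 2) { out[[tp]] <- NULL; next }
    sub <- lv[, cols, drop = FALSE]
    const <- apply(sub, 2, function(z) stats::sd(z) == 0)
    if (any(const))
      warning(sprintf("constant log2 profile in timepoint %s; r reported as NA",
                      tp))
    r <- suppressWarnings(stats::cor(sub))
    r[const, ] <- NA
    r[, const] <- NA
    diag(r) <- ifelse(const, NA, 1)
    out[[tp]] <- r
  }
  out
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when its (replicate-averaged) FPKM reaches
#' `fpkm_min` at one or more timepoints.
#'
#' @param x `expr_set` of FPKM values (typically timepoint-averaged).
#' @param fpkm_min detection threshold, default 1.
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(x, fpkm_min = 1) {
  stopifnot(inherits(x, "expr_set"))
  if (x$unit != "fpkm") stop("filter_expressed expects FPKM data")
  keep <- apply(x$values, 1, max) >= fpkm_min
  rownames(x$values)[keep]
}

#' Average replicates per timepoint
#'
#' Arithmetic mean of the replicate columns for each timepoint, on the
#' FPKM scale (averaging must precede any log transform). Unequal
#' replicate counts per timepoint are supported.
#'
#' @param x `expr_set` with `unit == "fpkm"`.
#' @return `expr_set` with one column per timepoint (replicate = 1).
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$unit != "fpkm") stop("average_replicates expects FPKM data")
  tps <- levels(x$sample_meta$timepoint)
  avg <- matrix(vapply(tps, function(tp) {
    cols <- x$sample_meta$sample[x$sample_meta$timepoint == tp]
    if (length(cols) == 0) stop(sprintf("timepoint %s has no samples", tp))
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values))), nrow = nrow(x$values))
  dimnames(avg) <- list(rownames(x$values), tps)
  expr_set(avg, unit = "fpkm",
           sample_meta = data.frame(sample = tps, timepoint = tps,
                                    replicate = 1L))
}

#' log2(FPKM + 1) transform
#'
#' @param x `expr_set` with `unit == "fpkm"`.
#' @return `expr_set` with `unit == "log2fpkm1"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (x$unit != "fpkm") stop("log_transform expects FPKM data")
  out <- x
  out$values <- log2(x$values + 1)
  out$unit <- "log2fpkm1"
  out
}
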