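#' Expression matrix container
#'
#' A light S3 wrapper around a dense gene x sample numeric matrix that tracks
#' the measurement unit. Rows are genes, columns are samples; dimnames carry
#' the identifiers and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @param unit one of `"counts"`, `"normlog"`, `"fpkm"`, `"zscore"`.
#' @return an `ExpressionMatrix` object.
#' @export
expr_matrix <- function(values, unit = c("counts", "normlog", "fpkm", "zscore")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene id: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample id: ", paste(dup_s, collapse = ", "))
  if (unit %in% c("counts", "fpkm") && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed when unit is '", unit, "'")
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [unit: %s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Gene and sample identifiers of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix by gene and/or sample identifiers
#'
#' @param m an `ExpressionMatrix`.
#' @param genes,samples identifier vectors (or indices); `NULL` keeps all.
#' @return an `ExpressionMatrix` with the same unit.
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expr_matrix(v, m$unit)
}

#' Median-of-ratios size factors
#'
#' Per-sample library-size factors computed as the median, over genes with a
#' positive geometric mean across samples, of the ratio of the sample's count
#' to that geometric mean. This is the classical count-normalization estimator
#' for RNA-seq and is robust to a minority of differentially expressed genes.
#'
#' @param m an `ExpressionMatrix` with unit `"counts"`.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("size_factors() requires unit 'counts'")
  cnt <- m$values
  log_geo <- rowMeans(log(cnt))            # -Inf for genes with any zero
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no gene has a positive count in every sample; cannot estimate size factors")
  sf <- apply(cnt, 2, function(x)
    exp(stats::median(log(x[usable]) - log_geo[usable])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("non-positive size factor estimated")
  sf
}

#' Normalized log2 expression
#'
#' Computes `log2(count / size_factor + pseudocount)` per gene and sample: a
#' monotone, variance-tamed transform of library-size-corrected counts used by
#' all downstream scoring, clustering and differential stages.
#'
#' @param m an `ExpressionMatrix` with unit `"counts"`.
#' @param factors per-sample size factors; estimated with [size_factors()]
#'   when `NULL`.
#' @param pseudocount value added before taking logs (default 1).
#' @return an `ExpressionMatrix` with unit `"normlog"`.
#' @export
normlog <- function(m, factors = NULL, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("normlog() requires unit 'counts'")
  if (is.null(factors)) factors <- size_factors(m)
  if (length(factors) != ncol(m$values))
    stop("length(factors) must equal the number of samples")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  v <- log2(sweep(m$values, 2, factors, "/") + pseudocount)
  expr_matrix(v, "normlog")
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm = count * 1e9 / (gene_length * column_total)` with the per-sample
#' column total taken over all genes in the matrix.
#'
#' @param m an `ExpressionMatrix` with unit `"counts"`.
#' @param annotation gene annotation table (see [read_annotation()]) supplying
#'   a `length` column in bp; every gene in `m` must be present.
#' @return an `ExpressionMatrix` with unit `"fpkm"`.
#' @export
fpkm <- function(m, annotation) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("fpkm() requires unit 'counts'")
  len <- annotation$length[match(gene_ids(m), annotation$gene_id)]
  if (any(is.na(len)))
    stop("missing gene length for: ",
         paste(utils::head(gene_ids(m)[is.na(len)], 5), collapse = ", "))
  if (any(len <= 0)) stop("gene lengths must be positive")
  tot <- colSums(m$values)
  if (any(tot <= 0)) stop("zero total counts in at least one sample")
  v <- sweep(m$values / len, 2, tot, "/") * 1e9
  expr_matrix(v, "fpkm")
}

#' Median-center an expression matrix
#'
#' Subtracts, from each gene (row) or sample (column), its median across the
#' other axis. The even-length median is the mean of the two middle values, so
#' centering is exact and idempotent.
#'
#' @param m an `ExpressionMatrix` or plain numeric matrix.
#' @param axis `"genes"` to center each gene across samples, `"samples"` to
#'   center each sample across genes.
#' @return object of the same type as `m`.
#' @export
median_center <- function(m, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  v <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (!is.matrix(v) || nrow(v) == 0L || ncol(v) == 0L)
    stop("cannot median-center an empty matrix")
  centered <- if (axis == "genes") {
    v - apply(v, 1, stats::median)
  } else {
    sweep(v, 2, apply(v, 2, stats::median), "-")
  }
  if (inherits(m, "ExpressionMatrix")) {
    m$values <- centered
    m
  } else centered
}
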