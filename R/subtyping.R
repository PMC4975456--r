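#' Select the most variable genes
#'
#' Ranks genes by variance of expression across samples after removing an
#' exclusion set (e.g. an immunoglobulin panel whose variance reflects
#' lymphocytic-thyroiditis infiltration rather than tumor signaling). Ties are
#' broken by lexicographic gene id so the selection is reproducible.
#'
#' @param m an `ExpressionMatrix` (normlog recommended).
#' @param n number of genes to keep (default 500).
#' @param exclude gene ids removed from the universe before ranking.
#' @param samples optional sample subset over which variance is computed.
#' @return character vector of up to `n` gene ids, most variable first.
#' @export
select_variable_genes <- function(m, n = 500, exclude = character(),
                                  samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), n >= 1)
  v <- m$values
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  v <- v[!rownames(v) %in% exclude, , drop = FALSE]
  vars <- apply(v, 1, stats::var)
  ord <- order(-vars, rownames(v))
  rownames(v)[ord][seq_len(min(n, nrow(v)))]
}

#' PCA embedding of samples
#'
#' Genes are mean-centered across samples (no scaling by default, the common
#' expression-PCA practice) and samples are projected onto the leading
#' principal components. For reproducibility each component's sign is fixed so
#' that its largest-magnitude gene loading is positive.
#'
#' @param m an `ExpressionMatrix`.
#' @param genes gene ids to use (e.g. from [select_variable_genes()]);
#'   default all.
#' @param n_components number of components to keep (default 2).
#' @param scale. logical; scale genes to unit variance before decomposition.
#' @return list with `scores` (sample x component matrix), `loadings`,
#'   `var_explained` (proportion per kept component) and `genes_used`.
#' @export
pca_embed <- function(m, genes = NULL, n_components = 2, scale. = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (n_components > min(dim(v)))
    stop("n_components exceeds min(genes, samples)")
  gene_var <- apply(v, 1, stats::var)
  if (all(gene_var == 0))
    stop("degenerate input: all genes have zero variance")
  if (scale. && any(gene_var == 0))
    stop("cannot scale zero-variance genes")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = scale.)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[k],
       genes_used = rownames(v))
}

# k-means++ style furthest-point-weighted seeding
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
    for (i in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[i] <- sample.int(n, 1, prob = prob)
      nd <- rowSums((x - matrix(x[centers[i], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of a sample embedding
#'
#' Lloyd/Hartigan-Wong iterations (via [stats::kmeans()]) from k-means++
#' seeding, repeated over `restarts` independent initializations; the
#' lowest-inertia solution is returned. Fully deterministic under `seed`.
#'
#' @param embedding sample x component numeric matrix (rownames = sample ids).
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param restarts number of random restarts (default 50).
#' @return integer vector of cluster ids (1..k), named by sample.
#' @export
kmeans_subtypes <- function(embedding, k = 3, seed = 1L, restarts = 50) {
  embedding <- as.matrix(embedding)
  if (k > nrow(embedding)) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be >= 1")
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- .kmeanspp_centers(embedding, k)
      km <- suppressWarnings(
        stats::kmeans(embedding, centers = centers, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  stats::setNames(best$cluster, rownames(embedding))
}

#' Name clusters by driver composition
#'
#' The cluster holding the plurality of BRAF-class drivers (BRAF point
#' mutation or fusion) is labeled BRAF-like; among the remaining clusters, the
#' plurality of H/K/NRAS drivers names RAS-like; everything else is NBNR.
#' A tied plurality leaves the tied clusters `unassigned` with a warning.
#'
#' @param clusters named integer vector from [kmeans_subtypes()].
#' @param drivers per-sample driver labels aligned with `clusters` (values
#'   such as `"BRAF"`, `"fusion"`, `"H/K/NRAS"`, `"other-small"`,
#'   `"driver-unknown"`).
#' @return data.frame with `sample_id`, `cluster`, `subtype`.
#' @export
label_clusters <- function(clusters, drivers) {
  stopifnot(length(clusters) == length(drivers))
  ids <- sort(unique(clusters))
  braf_n <- vapply(ids, function(cl)
    sum(drivers[clusters == cl] %in% c("BRAF", "fusion")), integer(1))
  ras_n <- vapply(ids, function(cl)
    sum(drivers[clusters == cl] == "H/K/NRAS"), integer(1))
  label <- stats::setNames(rep("NBNR", length(ids)), ids)

  pick <- function(counts, eligible) {
    counts[!eligible] <- -1L
    top <- max(counts)
    if (top <= 0) return(list(winner = integer(0), tied = integer(0)))
    w <- which(counts == top)
    if (length(w) > 1) list(winner = integer(0), tied = w)
    else list(winner = w, tied = integer(0))
  }

  eligible <- rep(TRUE, length(ids))
  pb <- pick(braf_n, eligible)
  if (length(pb$tied)) {
    warning("tied BRAF-class plurality; tied clusters left unassigned")
    label[pb$tied] <- "unassigned"
    eligible[pb$tied] <- FALSE
  } else if (length(pb$winner)) {
    label[pb$winner] <- "BRAF-like"
    eligible[pb$winner] <- FALSE
  }
  pr <- pick(ras_n, eligible)
  if (length(pr$tied)) {
    warning("tied H/K/NRAS plurality; tied clusters left unassigned")
    label[pr$tied] <- "unassigned"
  } else if (length(pr$winner)) {
    label[pr$winner] <- "RAS-like"
  }

  data.frame(sample_id = names(clusters),
             cluster = unname(clusters),
             subtype = unname(label[as.character(clusters)]),
             stringsAsFactors = FALSE)
}

#' Full molecular-subtyping pipeline
#'
#' Variable-gene selection (with exclusion set), PCA embedding, K-means
#' clustering and driver-based cluster naming in one call.
#'
#' @param m an `ExpressionMatrix` with unit `"normlog"` (tumor samples).
#' @param drivers per-sample driver labels aligned with `sample_ids(m)`.
#' @param n_genes number of variable genes (default 500).
#' @param exclude gene ids excluded from the variable-gene universe.
#' @param k number of clusters (default 3).
#' @param n_components number of principal components fed to K-means
#'   (default 2, the PC1/PC2 plane).
#' @param seed,restarts clustering reproducibility controls.
#' @return list with `result` (sample_id, cluster, subtype), `embedding`,
#'   `genes_used`, `k` and `seed`.
#' @export
subtype_cohort <- function(m, drivers, n_genes = 500, exclude = character(),
                           k = 3, n_components = 2, seed = 1L, restarts = 50) {
  genes <- select_variable_genes(m, n = n_genes, exclude = exclude)
  emb <- pca_embed(m, genes = genes, n_components = n_components)
  cl <- kmeans_subtypes(emb$scores, k = k, seed = seed, restarts = restarts)
  res <- label_clusters(cl, drivers)
  list(result = res, embedding = emb$scores, genes_used = genes,
       k = k, seed = seed)
}

#' Subtype-by-aggressiveness contingency
#'
#' Cross-tabulates subtype labels against a binary pathology flag (lymph node
#' metastasis or extrathyroidal extension), reports per-subtype frequencies,
#' and tests association with Pearson's chi-square, or Fisher's exact test
#' when any expected cell count is below 5.
#'
#' @param subtypes character vector of subtype labels.
#' @param flags logical vector, aligned with `subtypes`.
#' @return list with `table`, `percent` (per-subtype percent flagged),
#'   `test` ("chi-square" or "Fisher") and `p`.
#' @export
aggressiveness_table <- function(subtypes, flags) {
  stopifnot(length(subtypes) == length(flags))
  keep <- !is.na(subtypes) & !is.na(flags)
  tab <- table(subtype = subtypes[keep], flag = factor(flags[keep], c(FALSE, TRUE)))
  res <- .assoc_test(tab)
  pct <- round_half_up(100 * tab[, "TRUE"] / rowSums(tab), 2)
  list(table = tab, percent = pct, test = res$test, p = res$p)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions, corrected for chance: 1 for identical
#' partitions (up to relabeling), about 0 for independent ones. Used to score
#' recovered subtypes against planted truth on synthetic cohorts.
#'
#' @param a,b equal-length label vectors.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
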