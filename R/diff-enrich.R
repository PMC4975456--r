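#' Differential-expression statistics between two sample groups
#'
#' Size factors are estimated on the combined groups (median-of-ratios);
#' `base_mean` is the mean of size-factor-normalized counts over all samples
#' in either group; `lfc` is `log2((meanA + pc) / (meanB + pc))` on normalized
#' means (positive = up in group A). P-values come from a two-sided Welch
#' t-test per gene on `log2(normalized + 1)` values — a calibrated stand-in
#' for a count-model test, exposed through the `test` hook — and are adjusted
#' across genes by Benjamini-Hochberg.
#'
#' @param m an `ExpressionMatrix` with unit `"counts"`.
#' @param group_a,group_b sample id vectors (each of size >= 2).
#' @param pseudocount added to normalized group means before the log ratio.
#' @param test either `"welch"` or a function `(matA, matB) -> p-vector`
#'   taking normalized-log expression matrices for an external count-model
#'   test.
#' @return data.frame with `gene_id`, `lfc`, `base_mean`, `p`, `q`.
#' @export
deg_stats <- function(m, group_a, group_b, pseudocount = 1, test = "welch") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("deg_stats() requires unit 'counts'")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  both <- c(group_a, group_b)
  sub <- em_subset(m, samples = both)
  sf <- size_factors(sub)
  norm <- sweep(sub$values, 2, sf, "/")
  base_mean <- rowMeans(norm)
  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  la <- log2(norm[, group_a, drop = FALSE] + 1)
  lb <- log2(norm[, group_b, drop = FALSE] + 1)
  p <- if (is.function(test)) test(la, lb) else .welch_rows(la, lb)
  data.frame(gene_id = gene_ids(sub), lfc = lfc, base_mean = base_mean,
             p = p, q = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# vectorized two-sided Welch t-test across rows
.welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: no within-group variance
  zero <- se2 == 0
  p[zero & ma == mb] <- 1
  p[zero & ma != mb] <- 0
  p
}

#' Classify differential-expression records by thresholds
#'
#' `up`: q < 0.05, lfc >= 1, base_mean >= 100; `down`: q < 0.05, lfc <= -1,
#' base_mean >= 100; `moderate-down`: q < 0.05 and -1 < lfc < 0 (no
#' expression floor); everything else `ns`. Fold-change and base-mean bounds
#' are inclusive.
#'
#' @param deg output of [deg_stats()].
#' @param lfc_cut,q_cut,base_mean_min classification thresholds.
#' @return `deg` with a `class` column.
#' @export
classify_deg <- function(deg, lfc_cut = 1, q_cut = 0.05, base_mean_min = 100) {
  sig <- deg$q < q_cut
  cls <- rep("ns", nrow(deg))
  cls[sig & deg$lfc >= lfc_cut & deg$base_mean >= base_mean_min] <- "up"
  cls[sig & deg$lfc <= -lfc_cut & deg$base_mean >= base_mean_min] <- "down"
  cls[sig & deg$lfc > -lfc_cut & deg$lfc < 0] <- "moderate-down"
  deg$class <- cls
  deg
}

#' Positional (chromosome-arm) over-representation of a gene set
#'
#' One-sided hypergeometric test per arm for over-representation of `genes`
#' among the arm's members within `universe`, with Benjamini-Hochberg
#' adjustment across arms. The natural universe is the set of genes that
#' survived expression filtering and entered the differential test.
#'
#' @param genes gene ids of interest (e.g. moderately downregulated genes).
#' @param annotation gene annotation table with an `arm` column.
#' @param universe gene ids defining the background.
#' @return data.frame sorted by p with `arm`, `overlap`, `arm_size`,
#'   `set_size`, `universe_size`, `p`, `q`, `rank`.
#' @export
positional_enrichment <- function(genes, annotation, universe) {
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  arm_of <- annotation$arm[match(universe, annotation$gene_id)]
  arms <- sort(unique(arm_of[!is.na(arm_of)]))
  n_u <- length(universe)
  n_s <- length(genes)
  res <- do.call(rbind, lapply(arms, function(a) {
    members <- universe[!is.na(arm_of) & arm_of == a]
    k <- length(intersect(genes, members))
    m_a <- length(members)
    p <- stats::phyper(k - 1, m_a, n_u - m_a, n_s, lower.tail = FALSE)
    data.frame(arm = a, overlap = k, arm_size = m_a, set_size = n_s,
               universe_size = n_u, p = p, stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$arm), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Pearson correlation between two genes' FPKM profiles
#'
#' @param m an `ExpressionMatrix` with unit `"fpkm"`.
#' @param gene_a,gene_b gene ids.
#' @param samples optional sample subset.
#' @return Pearson r.
#' @export
gene_pair_correlation <- function(m, gene_a, gene_b, samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(samples)) samples <- sample_ids(m)
  stats::cor(m$values[gene_a, samples], m$values[gene_b, samples],
             method = "pearson")
}

#' Flag samples overexpressing a gene
#'
#' Samples whose normalized-log expression of `gene` exceeds the cohort mean
#' by more than `z_cut` standard deviations (both computed over the supplied
#' samples). A simple outlier rule for delimiting, e.g., an
#' ESRRA-overexpression group.
#'
#' @param m an `ExpressionMatrix` with unit `"normlog"`.
#' @param gene gene id.
#' @param samples optional sample subset (typically tumors).
#' @param z_cut threshold in sd units (default 2).
#' @return character vector of flagged sample ids.
#' @export
flag_overexpressed <- function(m, gene, samples = NULL, z_cut = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "normlog") stop("flag_overexpressed() requires unit 'normlog'")
  if (is.null(samples)) samples <- sample_ids(m)
  x <- m$values[gene, samples]
  names(x)[x > mean(x) + z_cut * stats::sd(x)]
}
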