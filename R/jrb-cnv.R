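#' Gene filter for jointly-regulated-block (JRB) analysis
#'
#' Keeps autosomal protein-coding genes whose mean FPKM across all supplied
#' samples is at least `min_mean_fpkm` (inclusive), returned sorted by
#' chromosomal coordinate. Chromosome names may carry a "chr" prefix or not.
#'
#' @param m an `ExpressionMatrix` with unit `"fpkm"`.
#' @param annotation gene annotation table.
#' @param min_mean_fpkm expression floor (default 1.5).
#' @return character vector of gene ids, coordinate-sorted.
#' @export
jrb_gene_filter <- function(m, annotation, min_mean_fpkm = 1.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "fpkm") stop("jrb_gene_filter() requires unit 'fpkm'")
  ann <- annotation[match(gene_ids(m), annotation$gene_id), ]
  chrom <- sub("^chr", "", ann$chrom)
  autosomal <- chrom %in% as.character(1:22)
  coding <- ann$biotype == "protein_coding"
  expressed <- rowMeans(m$values) >= min_mean_fpkm
  keep <- which(autosomal & coding & expressed & !is.na(ann$gene_id))
  if (!length(keep)) stop("no gene survives the JRB filter")
  keep <- keep[order(as.integer(chrom[keep]), ann$start[keep])]
  ann$gene_id[keep]
}

#' Reference log-FPKM statistics from normal tissues
#'
#' Per-gene mean and standard deviation (denominator n-1) of
#' `log(FPKM + pseudocount)` across the reference normal samples. Genes with
#' zero standard deviation are flagged; they carry no scale information and
#' are excluded from tumor scoring.
#'
#' @param m_normals an `ExpressionMatrix` with unit `"fpkm"`, normal samples
#'   only.
#' @param pseudocount added to FPKM before the natural log (default 0.1; the
#'   log base cancels in downstream Z-scores).
#' @return a `NormalReferenceStats` list: `mu`, `sigma`, `n_reference`,
#'   `flagged` (sigma-zero gene ids), `pseudocount`.
#' @export
jrb_reference <- function(m_normals, pseudocount = 0.1) {
  stopifnot(inherits(m_normals, "ExpressionMatrix"))
  if (m_normals$unit != "fpkm") stop("jrb_reference() requires unit 'fpkm'")
  lv <- log(m_normals$values + pseudocount)
  mu <- rowMeans(lv)
  sigma <- apply(lv, 1, stats::sd)
  structure(list(mu = mu, sigma = sigma, n_reference = ncol(lv),
                 flagged = names(sigma)[sigma == 0],
                 pseudocount = pseudocount),
            class = "NormalReferenceStats")
}

#' Two-stage Z-score transform of tumor expression
#'
#' Stage 1 standardizes each gene's `log(FPKM + pseudocount)` against the
#' normal-tissue reference: `Z = (log(FPKM) - mu) / sigma`. Stage 2
#' standardizes each tumor sample across genes: `ZZ = (Z - mu_i) / sigma_i`
#' where `mu_i`, `sigma_i` are the sample's mean and sd (denominator n-1) of
#' Z. After stage 2 every tumor column has mean 0 and sd 1, removing global
#' per-sample shifts so only relative arm-level structure remains.
#'
#' @param m_tumors an `ExpressionMatrix` with unit `"fpkm"`, tumor samples.
#' @param ref a `NormalReferenceStats` from [jrb_reference()].
#' @return list with `zz` (gene x tumor matrix, sigma-zero genes dropped),
#'   `stage = "ZZ"`, `mu_i`, `sigma_i`.
#' @export
zz_transform <- function(m_tumors, ref) {
  stopifnot(inherits(m_tumors, "ExpressionMatrix"),
            inherits(ref, "NormalReferenceStats"))
  if (m_tumors$unit != "fpkm") stop("zz_transform() requires unit 'fpkm'")
  genes <- intersect(gene_ids(m_tumors), names(ref$mu))
  genes <- setdiff(genes, ref$flagged)
  if (!length(genes)) stop("no scorable gene (all flagged or absent from reference)")
  lv <- log(m_tumors$values[genes, , drop = FALSE] + ref$pseudocount)
  z <- (lv - ref$mu[genes]) / ref$sigma[genes]
  mu_i <- colMeans(z)
  sigma_i <- apply(z, 2, stats::sd)
  if (any(sigma_i == 0))
    stop("sample(s) with zero Z-score dispersion: ",
         paste(colnames(z)[sigma_i == 0], collapse = ", "))
  zz <- sweep(sweep(z, 2, mu_i, "-"), 2, sigma_i, "/")
  list(zz = zz, stage = "ZZ", mu_i = mu_i, sigma_i = sigma_i)
}

#' Arm-level JRB calls
#'
#' Per tumor sample: the arm value is the median ZZ over the arm's genes;
#' values are then median-centered across the callable arms (those with at
#' least `min_genes` scorable genes); an arm with centered value >=
#' `threshold` is called overexpressed and <= `-threshold` underexpressed
#' (inclusive thresholds). Arms below `min_genes` are `no-call` and excluded
#' from the cross-arm median.
#'
#' @param zz output of [zz_transform()].
#' @param annotation gene annotation table with an `arm` column.
#' @param min_genes minimum scorable genes for a callable arm (default 10).
#' @param threshold call threshold on the centered arm value (default 0.5).
#' @return an `ArmCallMatrix` list: `values` (sample x arm centered medians,
#'   `NA` for no-call arms), `calls` (character matrix over
#'   overexpressed/underexpressed/neutral/no-call), `genes_per_arm`.
#' @export
call_arms <- function(zz, annotation, min_genes = 10, threshold = 0.5) {
  gene_arm <- annotation$arm[match(rownames(zz$zz), annotation$gene_id)]
  if (any(is.na(gene_arm)))
    stop("genes missing arm annotation: ",
         paste(utils::head(rownames(zz$zz)[is.na(gene_arm)], 5), collapse = ", "))
  arms <- sort(unique(gene_arm))
  genes_per_arm <- vapply(arms, function(a) sum(gene_arm == a), integer(1))
  callable <- arms[genes_per_arm >= min_genes]
  if (length(callable) < 3)
    stop("fewer than 3 callable arms; cross-arm median-centering is meaningless")
  samples <- colnames(zz$zz)
  med <- matrix(NA_real_, length(samples), length(arms),
                dimnames = list(samples, arms))
  for (a in callable)
    med[, a] <- apply(zz$zz[gene_arm == a, , drop = FALSE], 2, stats::median)
  centered <- med - apply(med[, callable, drop = FALSE], 1, stats::median)
  calls <- matrix("no-call", length(samples), length(arms),
                  dimnames = list(samples, arms))
  calls[, callable] <- "neutral"
  calls[!is.na(centered) & centered >= threshold] <- "overexpressed"
  calls[!is.na(centered) & centered <= -threshold] <- "underexpressed"
  structure(list(values = centered, calls = calls,
                 genes_per_arm = genes_per_arm, threshold = threshold,
                 min_genes = min_genes),
            class = "ArmCallMatrix")
}

#' @export
print.ArmCallMatrix <- function(x, ...) {
  cat(sprintf("ArmCallMatrix: %d samples x %d arms (%d callable)\n",
              nrow(x$values), ncol(x$values),
              sum(x$genes_per_arm >= x$min_genes)))
  tab <- table(x$calls)
  cat(paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy arm calls
#'
#' @param x an `ArmCallMatrix`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with `sample`, `arm`, `centered_value`, `call`,
#'   `n_genes`.
#' @export
as.data.frame.ArmCallMatrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    sample = rep(rownames(x$values), times = ncol(x$values)),
    arm = rep(colnames(x$values), each = nrow(x$values)),
    centered_value = as.vector(x$values),
    call = as.vector(x$calls),
    n_genes = rep(unname(x$genes_per_arm), each = nrow(x$values)),
    stringsAsFactors = FALSE
  )
}

#' Full JRB pipeline: FPKM matrix to arm-level CNV calls
#'
#' Filters genes ([jrb_gene_filter()]), builds the normal reference
#' ([jrb_reference()]), applies the two-stage Z transform ([zz_transform()])
#' and calls arms ([call_arms()]).
#'
#' @param m an `ExpressionMatrix` with unit `"fpkm"`, tumors and normals.
#' @param annotation gene annotation table.
#' @param normal_ids,tumor_ids sample id vectors.
#' @param min_mean_fpkm,pseudocount,min_genes,threshold stage parameters.
#' @return an `ArmCallMatrix`.
#' @export
jrb_pipeline <- function(m, annotation, normal_ids, tumor_ids,
                         min_mean_fpkm = 1.5, pseudocount = 0.1,
                         min_genes = 10, threshold = 0.5) {
  genes <- jrb_gene_filter(m, annotation, min_mean_fpkm = min_mean_fpkm)
  ref <- jrb_reference(em_subset(m, genes, normal_ids), pseudocount = pseudocount)
  zz <- zz_transform(em_subset(m, genes, tumor_ids), ref)
  call_arms(zz, annotation, min_genes = min_genes, threshold = threshold)
}

#' Write arm calls and a BED of called segments
#'
#' The TSV holds one row per (sample, arm); the BED lists whole-arm intervals
#' (0-based half-open, spanning the arm's first to last annotated gene) for
#' every non-neutral call.
#'
#' @param x an `ArmCallMatrix`.
#' @param annotation gene annotation table (for arm intervals).
#' @param path output TSV path; the BED is written next to it with a `.bed`
#'   extension.
#' @return named vector of written paths, invisibly.
#' @export
write_arm_calls <- function(x, annotation, path) {
  df <- as.data.frame(x)
  data.table::fwrite(df, path, sep = "\t")
  seg <- df[df$call %in% c("overexpressed", "underexpressed"), ]
  bed_path <- paste0(tools::file_path_sans_ext(path), ".bed")
  if (nrow(seg)) {
    span <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      g <- annotation[annotation$arm == seg$arm[i], ]
      data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
                 name = sprintf("%s|%s|%s", seg$sample[i], seg$arm[i], seg$call[i]),
                 score = round(seg$centered_value[i], 4),
                 stringsAsFactors = FALSE)
    }))
    data.table::fwrite(span, bed_path, sep = "\t", col.names = FALSE)
  } else writeLines(character(0), bed_path)
  invisible(c(tsv = path, bed = bed_path))
}
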