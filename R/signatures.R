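#' Gene panel
#'
#' An ordered set of unique gene ids with a name. The thyroid differentiation
#' score (TDS) panel conventionally holds 16 thyroid metabolism and function
#' genes and the ERK panel 52 MAPK-pathway genes; both memberships are
#' configuration, not code, and synthetic analyses use generator-defined
#' panels.
#'
#' @param gene_ids character vector of unique gene identifiers.
#' @param name panel name, e.g. `"TDS"`, `"ERK"` or `"custom"`.
#' @return a `GenePanel` object.
#' @export
gene_panel <- function(gene_ids, name = "custom") {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("a gene panel cannot be empty")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id in panel: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  structure(list(name = name, gene_ids = gene_ids), class = "GenePanel")
}

#' @export
print.GenePanel <- function(x, ...) {
  cat(sprintf("GenePanel '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

#' Per-sample gene-signature score
#'
#' For each panel gene present in the matrix, expression is median-centered
#' across the scored (tumor) samples; the per-sample score is then the mean of
#' the centered values over the panel genes. With a TDS panel this is the
#' thyroid differentiation score; with an ERK panel, the ERK/MAPK activation
#' score. Centering is computed over the scored subset only, never including
#' normals, so scores are cohort-relative.
#'
#' @param m an `ExpressionMatrix` with unit `"normlog"`.
#' @param panel a `GenePanel`.
#' @param samples sample ids to score (typically the tumors); default all.
#' @return data.frame with `sample_id`, `panel`, `score`, `n_genes_used`.
#'   Panel genes missing from the matrix are dropped and reflected in
#'   `n_genes_used`.
#' @export
signature_score <- function(m, panel, samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(panel, "GenePanel"))
  if (m$unit != "normlog") stop("signature_score() requires unit 'normlog'")
  if (is.null(samples)) samples <- sample_ids(m)
  if (!length(samples)) stop("at least one sample is required")
  missing_s <- setdiff(samples, sample_ids(m))
  if (length(missing_s))
    stop("samples not in matrix: ", paste(missing_s, collapse = ", "))
  present <- intersect(panel$gene_ids, gene_ids(m))
  if (!length(present))
    stop("no gene of panel '", panel$name, "' is present in the matrix")
  dropped <- setdiff(panel$gene_ids, present)
  if (length(dropped))
    message(sprintf("panel '%s': %d of %d genes absent from the matrix",
                    panel$name, length(dropped), length(panel$gene_ids)))
  v <- m$values[present, samples, drop = FALSE]
  centered <- v - apply(v, 1, stats::median)
  data.frame(sample_id = samples,
             panel = panel$name,
             score = colMeans(centered),
             n_genes_used = length(present),
             row.names = NULL,
             stringsAsFactors = FALSE)
}
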