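#' Read a gene x sample count matrix
#'
#' Two dialects are supported: a TSV with gene ids in the first column and one
#' column per sample, and a MatrixMarket triplet (`.mtx`) accompanied by
#' `<path>.genes.tsv` / `<path>.samples.tsv` index files (one identifier per
#' line, matching the writer's convention).
#'
#' @param path file path (the `.mtx` file itself for `dialect = "mtx"`).
#' @param dialect `"tsv"` or `"mtx"`.
#' @param strict when `TRUE`, non-integer values are an error.
#' @return an `ExpressionMatrix` with unit `"counts"`.
#' @export
read_counts <- function(path, dialect = c("tsv", "mtx"), strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2) stop("malformed counts header in ", path)
    genes <- as.character(dt[[1]])
    v <- as.matrix(dt[, -1, drop = FALSE])
    rownames(v) <- genes
  } else {
    v <- as.matrix(Matrix::readMM(path))
    rownames(v) <- readLines(paste0(path, ".genes.tsv"))
    colnames(v) <- readLines(paste0(path, ".samples.tsv"))
  }
  storage.mode(v) <- "double"
  dup <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup)) stop("duplicated gene id: ", paste(dup, collapse = ", "))
  if (strict && any(v != round(v)))
    stop("non-integer counts found in ", path)
  message(sprintf("read %d genes x %d samples from %s", nrow(v), ncol(v), path))
  expr_matrix(v, "counts")
}

#' Write a count matrix
#'
#' @param m an `ExpressionMatrix` (any unit is written as-is; the TSV header
#'   row holds the sample ids).
#' @param path destination path.
#' @param dialect `"tsv"` or `"mtx"` (the latter also writes
#'   `<path>.genes.tsv` and `<path>.samples.tsv`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, dialect = c("tsv", "mtx")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (dialect == "tsv") {
    dt <- data.table::data.table(gene_id = gene_ids(m))
    dt <- cbind(dt, data.table::as.data.table(m$values))
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(gene_ids(m), paste0(path, ".genes.tsv"))
    writeLines(sample_ids(m), paste0(path, ".samples.tsv"))
  }
  invisible(path)
}

# canonical annotation columns; coordinates are 0-based half-open internally
.ann_cols <- c("gene_id", "chrom", "start", "end", "strand", "biotype",
               "length", "arm")

.validate_annotation <- function(ann) {
  miss <- setdiff(.ann_cols, names(ann))
  if (length(miss)) stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("gene_id", "chrom", "strand", "biotype", "arm"))
    ann[[col]] <- as.character(ann[[col]])
  for (col in c("start", "end", "length"))
    ann[[col]] <- as.integer(ann[[col]])
  if (any(ann$start >= ann$end)) stop("annotation has start >= end")
  if (any(ann$length <= 0)) stop("annotation has non-positive gene length")
  ann
}

#' Read a gene annotation table
#'
#' The BED-like TSV dialect stores 0-based half-open coordinates and is read
#' verbatim; GTF (1-based closed, parsed with rtracklayer) is converted to the
#' internal 0-based half-open convention on read. Both carry gene id, biotype,
#' transcript length and chromosome-arm assignment.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gtf"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `length`, `arm`.
#' @export
read_annotation <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    ann <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    ann <- data.frame(
      gene_id = gr$gene_id,
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      start   = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
      end     = GenomicRanges::end(gr),
      strand  = as.character(GenomicRanges::strand(gr)),
      biotype = gr$gene_biotype,
      length  = as.integer(gr$gene_length),
      arm     = gr$arm,
      stringsAsFactors = FALSE
    )
  }
  ann <- .validate_annotation(ann)
  message(sprintf("read annotation for %d genes from %s", nrow(ann), path))
  ann
}

#' Write a gene annotation table
#'
#' @param ann annotation data.frame (internal 0-based half-open coordinates).
#' @param path destination path.
#' @param format `"tsv"` (written verbatim) or `"gtf"` (converted to 1-based
#'   closed coordinates on write).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  .validate_annotation(ann)
  if (format == "tsv") {
    data.table::fwrite(ann, path, sep = "\t")
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
      strand = ann$strand
    )
    gr$type <- "gene"
    gr$source <- "thyrotype"
    gr$gene_id <- ann$gene_id
    gr$gene_biotype <- ann$biotype
    gr$gene_length <- ann$length
    gr$arm <- ann$arm
    rtracklayer::export(gr, path, format = "gtf")
  }
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' TSV with at least `sample_id` and `role` (`tumor`/`normal`); typical
#' columns also include `histology`, `lt`, `age`, `sex`, `menopause`,
#' `smoking`, `drinking` and `matched_normal_id`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "role") %in% names(md)))
    stop("metadata must contain 'sample_id' and 'role' columns")
  if (!all(md$role %in% c("tumor", "normal")))
    stop("metadata 'role' must be 'tumor' or 'normal'")
  if ("matched_normal_id" %in% names(md)) {
    ref <- md$matched_normal_id[!is.na(md$matched_normal_id) & md$matched_normal_id != ""]
    bad <- setdiff(ref, md$sample_id[md$role == "normal"])
    if (length(bad))
      stop("matched_normal_id does not reference a normal sample: ",
           paste(bad, collapse = ", "))
  }
  message(sprintf("read metadata for %d samples from %s", nrow(md), path))
  md
}

#' @rdname read_metadata
#' @param md metadata data.frame.
#' @export
write_metadata <- function(md, path) {
  data.table::fwrite(md, path, sep = "\t")
  invisible(path)
}

#' Read a gene panel file
#'
#' One gene id per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @param name panel name (defaults to the file name without extension).
#' @return a `GenePanel` (see [gene_panel()]).
#' @export
read_panel <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids)]
  gene_panel(ids, name = name)
}

#' Read a variant table
#'
#' TSV columns: `sample`, `gene`, `hgvs_p`, `consequence`, `maf_exac`,
#' `maf_1kg`, `maf_esp`, `in_driver_list`. The minimal VCF dialect stores the
#' same fields in INFO keys (`SAMPLE`, `GENE`, `HGVSP`, `CSQ`, `MAF_EXAC`,
#' `MAF_1KG`, `MAF_ESP`, `DRIVER`), one record per sample-variant pair.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return data.frame of variant records.
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    v <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
    inf <- VariantAnnotation::info(vcf)
    as_chr <- function(x) as.character(unlist(x))
    as_num <- function(x) suppressWarnings(as.numeric(unlist(x)))
    v <- data.frame(
      sample = as_chr(inf$SAMPLE),
      gene = as_chr(inf$GENE),
      hgvs_p = as_chr(inf$HGVSP),
      consequence = as_chr(inf$CSQ),
      maf_exac = as_num(inf$MAF_EXAC),
      maf_1kg = as_num(inf$MAF_1KG),
      maf_esp = as_num(inf$MAF_ESP),
      in_driver_list = as.logical(unlist(inf$DRIVER)),
      stringsAsFactors = FALSE
    )
  }
  message(sprintf("read %d variant records from %s", nrow(v), path))
  v
}

.empty_variants <- function() {
  data.frame(sample = character(), gene = character(), hgvs_p = character(),
             consequence = character(), maf_exac = numeric(),
             maf_1kg = numeric(), maf_esp = numeric(),
             in_driver_list = logical(), stringsAsFactors = FALSE)
}

.empty_fusions <- function() {
  data.frame(sample = character(), geneA = character(), geneB = character(),
             chromA = character(), posA = integer(), chromB = character(),
             posB = integer(), discordant_pairs = integer(),
             found_in_normal = logical(), stringsAsFactors = FALSE)
}

#' Read a fusion-candidate table
#'
#' TSV columns: `sample`, `geneA`, `geneB`, `chromA`, `posA`, `chromB`,
#' `posB`, `discordant_pairs`, `found_in_normal`.
#'
#' @param path file path.
#' @return data.frame of fusion candidates.
#' @export
read_fusions <- function(path) {
  f <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  message(sprintf("read %d fusion candidates from %s", nrow(f), path))
  f
}
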