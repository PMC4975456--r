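.NONSILENT <- c("nonsynonymous", "splice-site", "frameshift-indel",
                "stop-gain", "stop-loss")

#' Driver SNV/indel filtration
#'
#' A record passes when all three criteria hold, checked in order:
#' 1. population frequency: every present MAF is within threshold
#'    (ExAC <= 1e-4; 1000 Genomes and ESP6500 <= 0.01, inclusive). A missing
#'    MAF counts as 0 — absence from population databases is evidence of
#'    rarity.
#' 2. consequence: nonsilent, i.e. nonsynonymous or splice-site SNVs and
#'    frameshift indels (stop-gain/stop-loss are treated as nonsilent).
#' 3. driver-list membership (`in_driver_list`, e.g. COSMIC70 or a TCGA PTC
#'    gene list supplied as an annotation flag).
#' The fail `reason` names the first violated criterion. Filtering is
#' idempotent: verdicts are recomputed from the record fields alone.
#'
#' @param variants data.frame with columns `consequence`, `maf_exac`,
#'   `maf_1kg`, `maf_esp`, `in_driver_list`.
#' @param maf_exac_max,maf_other_max inclusive frequency ceilings.
#' @return `variants` with `verdict` (`"pass"`/`"fail"`) and `reason` columns.
#' @export
filter_snv_indel <- function(variants, maf_exac_max = 1e-4,
                             maf_other_max = 0.01) {
  v <- variants
  maf0 <- function(x) ifelse(is.na(x), 0, x)
  freq_ok <- maf0(v$maf_exac) <= maf_exac_max &
    maf0(v$maf_1kg) <= maf_other_max &
    maf0(v$maf_esp) <= maf_other_max
  cons_ok <- v$consequence %in% .NONSILENT
  list_ok <- as.logical(v$in_driver_list)
  v$verdict <- ifelse(freq_ok & cons_ok & list_ok, "pass", "fail")
  v$reason <- ifelse(!freq_ok, "population_frequency",
              ifelse(!cons_ok, "consequence",
              ifelse(!list_ok, "not_in_driver_list", NA_character_)))
  v
}

#' Fusion-candidate filtration
#'
#' A candidate passes when, checked in order:
#' 1. it is seen only in tumor samples (`found_in_normal` is FALSE);
#' 2. discordant read pairs between the two partners >= `min_discordant`
#'    (default 2, inclusive);
#' 3. the partners lie on different chromosomes, or the genomic distance
#'    between predicted breakpoints is >= `min_distance` (default 100 kb,
#'    inclusive).
#'
#' @param fusions data.frame with columns `chromA`, `posA`, `chromB`, `posB`,
#'   `discordant_pairs`, `found_in_normal`.
#' @param min_discordant,min_distance inclusive thresholds.
#' @return `fusions` with `verdict` and `reason` columns.
#' @export
filter_fusions <- function(fusions, min_discordant = 2, min_distance = 1e5) {
  f <- fusions
  tumor_only <- !as.logical(f$found_in_normal)
  support_ok <- f$discordant_pairs >= min_discordant
  dist_ok <- as.character(f$chromA) != as.character(f$chromB) |
    abs(as.numeric(f$posA) - as.numeric(f$posB)) >= min_distance
  f$verdict <- ifelse(tumor_only & support_ok & dist_ok, "pass", "fail")
  f$reason <- ifelse(!tumor_only, "found_in_normal",
              ifelse(!support_ok, "discordant_pairs",
              ifelse(!dist_ok, "breakpoint_distance", NA_character_)))
  f
}

#' Mutual-exclusivity contingency for two altered genes
#'
#' Tabulates samples altered in both, either, or neither gene and tests for a
#' co-occurrence deficit with a one-sided Fisher's exact test (alternative:
#' odds ratio < 1, i.e. fewer co-altered samples than expected).
#'
#' @param alterations logical sample x gene matrix of alteration flags.
#' @param gene_a,gene_b column names to compare.
#' @return list with `counts` (2x2 matrix: A yes/no by B yes/no) and `p`.
#' @export
exclusivity_table <- function(alterations, gene_a, gene_b) {
  a <- as.logical(alterations[, gene_a])
  b <- as.logical(alterations[, gene_b])
  counts <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(A = c("altered", "wild-type"),
                                   B = c("altered", "wild-type")))
  p <- stats::fisher.test(counts, alternative = "less")$p.value
  list(counts = counts, p = p)
}

#' Assign each sample a driver group
#'
#' From filter-passing records, samples are grouped with precedence
#' fusion > BRAF > H/K/NRAS > other-small; samples with no passing record are
#' `driver-unknown`. Alterations are expected to be mutually exclusive, so a
#' sample hitting multiple classes triggers a warning before precedence is
#' applied.
#'
#' @param sample_ids character vector of tumor sample ids.
#' @param variants variant table with `verdict` (from [filter_snv_indel()]).
#' @param fusions fusion table with `verdict` (from [filter_fusions()]).
#' @param braf_genes,ras_genes gene symbols defining the BRAF and H/K/NRAS
#'   classes.
#' @return named character vector of groups, one per sample.
#' @export
assign_driver_group <- function(sample_ids, variants, fusions,
                                braf_genes = "BRAF",
                                ras_genes = c("HRAS", "KRAS", "NRAS")) {
  pv <- variants[variants$verdict == "pass", , drop = FALSE]
  pf <- fusions[fusions$verdict == "pass", , drop = FALSE]
  out <- stats::setNames(rep("driver-unknown", length(sample_ids)), sample_ids)
  for (sid in sample_ids) {
    has <- c(
      fusion = sid %in% pf$sample,
      BRAF = any(pv$sample == sid & pv$gene %in% braf_genes),
      `H/K/NRAS` = any(pv$sample == sid & pv$gene %in% ras_genes),
      `other-small` = any(pv$sample == sid & !pv$gene %in% c(braf_genes, ras_genes))
    )
    if (sum(has) > 1)
      warning("sample ", sid, " has passing records in multiple driver classes (",
              paste(names(has)[has], collapse = ", "),
              "); applying precedence fusion > BRAF > H/K/NRAS > other-small")
    if (any(has)) out[sid] <- names(has)[which(has)[1]]
  }
  out
}
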