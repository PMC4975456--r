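#' Chromosome-arm labels for a synthetic genome
#'
#' Autosomal arms in karyotype order, omitting the five acrocentric short
#' arms (13p, 14p, 15p, 21p, 22p) that carry no annotated protein-coding
#' genes — which leaves exactly 39 arms, "1p" through "22q". The first
#' `n_arms` labels are used.
#'
#' @param n_arms number of arms (at most 39).
#' @return character vector of arm labels.
#' @export
arm_names <- function(n_arms) {
  all_arms <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  all_arms <- setdiff(all_arms, c("13p", "14p", "15p", "21p", "22p"))
  if (n_arms > length(all_arms))
    stop("at most ", length(all_arms), " autosomal arms are supported")
  all_arms[seq_len(n_arms)]
}

#' Configuration for a synthetic thyroid-tumor cohort
#'
#' Defines the generative model: negative-binomial counts with log-normal
#' per-gene base means, log-normal per-sample library sizes, and multiplicative
#' (log2-additive) planted programs — per-subtype expression programs, the
#' ERK-up/TDS-down axis of BRAF-like tumors, an immunoglobulin program in
#' lymphocytic-thyroiditis (LT) samples, an oncocytic mitochondrial program
#' (including ESRRA/PPARGC1A analogues and a TCA-cycle set), and arm-level
#' dosage shifts from `cnv_plan`. Defaults mirror a cohort of 180 tumors and
#' 81 normals with subtype sizes 81/53/46 (BRAF-like/RAS-like/NBNR), 29% LT
#' prevalence, and oncocytic tumors arising only within NBNR (about 6 of 180).
#'
#' @param n_tumors,n_normals sample counts.
#' @param n_arms,genes_per_arm genome layout; `n_genes = n_arms * genes_per_arm`.
#' @param subtype_fractions named simplex over `BRAF-like`, `RAS-like`, `NBNR`.
#' @param base_mean_log `c(meanlog, sdlog)` of the log-normal base-mean
#'   distribution (natural-log scale of the NB mean).
#' @param dispersion negative-binomial dispersion (NB `size = 1/dispersion`).
#' @param libsize_sdlog sd of log-normal per-sample library-size factors.
#' @param panel_sizes named counts: `tds` (16), `erk` (52), `ig`, `oncocytic`,
#'   `program` (per-subtype program panel size).
#' @param effect_sizes named log2-fold-change magnitudes: `program`, `erk`,
#'   `tds` (applied downward), `ig`, `oncocytic`.
#' @param lt_prob probability a tumor carries the LT/immunoglobulin program.
#' @param oncocytic_prob probability an NBNR tumor is oncocytic.
#' @param cnv_plan list of `list(arm=, log2fc=, carrier_fraction=)` arm dosage
#'   events applied to random tumors.
#' @param seed integer; fully determines the generated cohort.
#' @return a validated `CohortConfig` list.
#' @export
cohort_config <- function(n_tumors = 180L,
                          n_normals = 81L,
                          n_arms = 39L,
                          genes_per_arm = 50L,
                          subtype_fractions = c("BRAF-like" = 81, "RAS-like" = 53,
                                                "NBNR" = 46) / 180,
                          base_mean_log = c(meanlog = 4, sdlog = 1.2),
                          dispersion = 0.05,
                          libsize_sdlog = 0.2,
                          panel_sizes = c(tds = 16L, erk = 52L, ig = 91L,
                                          oncocytic = 40L, program = 60L),
                          effect_sizes = c(program = 1, erk = 1, tds = 1,
                                           ig = 2, oncocytic = 2),
                          lt_prob = 0.29,
                          oncocytic_prob = 0.13,
                          cnv_plan = list(list(arm = "22q", log2fc = -0.6,
                                               carrier_fraction = 0.2)),
                          seed = 1L) {
  cfg <- list(n_tumors = as.integer(n_tumors), n_normals = as.integer(n_normals),
              n_arms = as.integer(n_arms), genes_per_arm = as.integer(genes_per_arm),
              subtype_fractions = subtype_fractions, base_mean_log = base_mean_log,
              dispersion = dispersion, libsize_sdlog = libsize_sdlog,
              panel_sizes = panel_sizes, effect_sizes = effect_sizes,
              lt_prob = lt_prob, oncocytic_prob = oncocytic_prob,
              cnv_plan = cnv_plan, seed = as.integer(seed))
  counts <- c(cfg$n_tumors, cfg$n_normals, cfg$n_arms, cfg$genes_per_arm)
  if (any(counts <= 0)) stop("all cohort counts must be positive")
  if (abs(sum(cfg$subtype_fractions) - 1) > 1e-9)
    stop("subtype_fractions must sum to 1")
  if (!setequal(names(cfg$subtype_fractions), c("BRAF-like", "RAS-like", "NBNR")))
    stop("subtype_fractions must be named BRAF-like, RAS-like, NBNR")
  need <- c("tds", "erk", "ig", "oncocytic", "program")
  if (!all(need %in% names(cfg$panel_sizes)))
    stop("panel_sizes must name: ", paste(need, collapse = ", "))
  arms <- arm_names(cfg$n_arms)
  for (ev in cfg$cnv_plan) {
    if (!ev$arm %in% arms)
      stop("cnv_plan arm not in the synthetic genome: ", ev$arm)
    if (ev$carrier_fraction < 0 || ev$carrier_fraction > 1)
      stop("cnv_plan carrier_fraction must be in [0, 1]")
  }
  n_panel <- sum(cfg$panel_sizes[c("tds", "erk", "ig", "oncocytic")]) +
    3L * cfg$panel_sizes[["program"]]
  cnv_arms <- vapply(cfg$cnv_plan, `[[`, character(1), "arm")
  n_free <- (cfg$n_arms - length(unique(cnv_arms))) * cfg$genes_per_arm
  if (n_panel > n_free)
    stop("not enough genes outside cnv_plan arms to host the planted panels")
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws counts from the generative model in [cohort_config()] and returns the
#' count matrix, gene annotation (0-based half-open coordinates, with arm
#' assignments and log-uniform transcript lengths in 500-100000 bp), sample
#' metadata, ground truth, and the planted gene panels. The same config (and
#' therefore the same seed) reproduces the output exactly.
#'
#' @param config a `CohortConfig`.
#' @return list with elements `counts` (`ExpressionMatrix`), `annotation`,
#'   `samples`, `truth` (per-tumor subtype/driver/lt/oncocytic plus the
#'   planted sample x arm log2 dosage matrix), `panels` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop("config must carry a single integer seed")
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  arms <- arm_names(cfg$n_arms)
  n_genes <- cfg$n_arms * cfg$genes_per_arm
  gene_arm <- rep(arms, each = cfg$genes_per_arm)
  gene_id <- sprintf("G%05d", seq_len(n_genes))

  ## panels live on arms untouched by the cnv plan so planted dosage and
  ## planted programs stay separable
  cnv_arms <- vapply(cfg$cnv_plan, `[[`, character(1), "arm")
  free_idx <- which(!gene_arm %in% cnv_arms)
  ps <- cfg$panel_sizes
  picks <- sample(free_idx,
                  ps[["tds"]] + ps[["erk"]] + ps[["ig"]] + ps[["oncocytic"]] +
                    3L * ps[["program"]])
  take <- function(n) {
    out <- picks[seq_len(n)]
    picks <<- picks[-seq_len(n)]
    out
  }
  idx_tds <- take(ps[["tds"]]); idx_erk <- take(ps[["erk"]])
  idx_ig <- take(ps[["ig"]]); idx_onc <- take(ps[["oncocytic"]])
  idx_prg <- list("BRAF-like" = take(ps[["program"]]),
                  "RAS-like" = take(ps[["program"]]),
                  "NBNR" = take(ps[["program"]]))
  ## name the oncocytic anchors and a TCA-cycle set after their real analogues
  gene_id[idx_onc[1]] <- "ESRRA"
  gene_id[idx_onc[2]] <- "PPARGC1A"
  n_tca <- min(10L, ps[["oncocytic"]] - 2L)
  if (n_tca > 0)
    gene_id[idx_onc[2 + seq_len(n_tca)]] <- sprintf("TCA%02d", seq_len(n_tca))
  panels <- list(tds = gene_id[idx_tds], erk = gene_id[idx_erk],
                 ig = gene_id[idx_ig], oncocytic = gene_id[idx_onc],
                 tca = gene_id[idx_onc[2 + seq_len(max(n_tca, 0))]],
                 programs = lapply(idx_prg, function(i) gene_id[i]))

  ## annotation: genes tiled along each chromosome, p arm then q arm
  gene_len <- round(exp(stats::runif(n_genes, log(500), log(1e5))))
  chrom <- sub("[pq]$", "", gene_arm)
  start <- integer(n_genes)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- i[gene_arm[i] == paste0(ch, "p")]
    q <- i[gene_arm[i] == paste0(ch, "q")]
    start[p] <- 10000L + (seq_along(p) - 1L) * 200000L
    cen <- 10000L + length(p) * 200000L + 3000000L   # synthetic centromere gap
    start[q] <- cen + (seq_along(q) - 1L) * 200000L
  }
  annotation <- data.frame(
    gene_id = gene_id, chrom = chrom, start = start,
    end = start + gene_len, strand = rep_len(c("+", "-"), n_genes),
    biotype = "protein_coding", length = gene_len, arm = gene_arm,
    stringsAsFactors = FALSE
  )

  ## samples and truth
  tum_id <- sprintf("T%03d", seq_len(cfg$n_tumors))
  nor_id <- sprintf("N%03d", seq_len(cfg$n_normals))
  n_sub <- .apportion(cfg$subtype_fractions, cfg$n_tumors)
  subtype <- sample(rep(names(n_sub), n_sub))
  driver <- vapply(subtype, .draw_driver, character(1))
  lt <- stats::runif(cfg$n_tumors) < cfg$lt_prob
  oncocytic <- subtype == "NBNR" & stats::runif(cfg$n_tumors) < cfg$oncocytic_prob

  arm_cnv <- matrix(0, cfg$n_tumors, cfg$n_arms,
                    dimnames = list(tum_id, arms))
  for (ev in cfg$cnv_plan) {
    n_car <- round(ev$carrier_fraction * cfg$n_tumors)
    carriers <- sample(cfg$n_tumors, n_car)
    arm_cnv[carriers, ev$arm] <- arm_cnv[carriers, ev$arm] + ev$log2fc
  }

  ## log2 effect matrix for tumors
  es <- cfg$effect_sizes
  eff <- matrix(0, n_genes, cfg$n_tumors, dimnames = list(gene_id, tum_id))
  onc_intensity <- stats::rnorm(cfg$n_tumors, 1, 0.15)
  for (j in seq_len(cfg$n_tumors)) {
    eff[idx_prg[[subtype[j]]], j] <- eff[idx_prg[[subtype[j]]], j] + es[["program"]]
    if (subtype[j] == "BRAF-like") {
      eff[idx_erk, j] <- eff[idx_erk, j] + es[["erk"]]
      eff[idx_tds, j] <- eff[idx_tds, j] - es[["tds"]]
    }
    if (lt[j]) eff[idx_ig, j] <- eff[idx_ig, j] + es[["ig"]]
    if (oncocytic[j])
      eff[idx_onc, j] <- eff[idx_onc, j] + es[["oncocytic"]] * onc_intensity[j]
    planted <- arm_cnv[j, ][gene_arm]
    eff[, j] <- eff[, j] + planted
  }

  base_mean <- stats::rlnorm(n_genes, cfg$base_mean_log[["meanlog"]],
                             cfg$base_mean_log[["sdlog"]])
  lib <- stats::rlnorm(cfg$n_tumors + cfg$n_normals, 0, cfg$libsize_sdlog)
  names(lib) <- c(tum_id, nor_id)

  mu_t <- base_mean * 2^eff
  mu_t <- sweep(mu_t, 2, lib[tum_id], "*")
  mu_n <- outer(base_mean, lib[nor_id])
  mu <- cbind(mu_t, mu_n)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow = n_genes,
                   dimnames = list(gene_id, c(tum_id, nor_id)))

  matched <- c(tum_id[seq_len(min(cfg$n_normals, cfg$n_tumors))],
               rep(NA_character_, max(0L, cfg$n_tumors - cfg$n_normals)))
  samples <- data.frame(
    sample_id = c(tum_id, nor_id),
    role = rep(c("tumor", "normal"), c(cfg$n_tumors, cfg$n_normals)),
    histology = c(.histology_for(subtype), rep(NA_character_, cfg$n_normals)),
    lt = c(lt, rep(FALSE, cfg$n_normals)),
    age = round(stats::rnorm(cfg$n_tumors + cfg$n_normals, 47, 13)),
    sex = sample(c("F", "M"), cfg$n_tumors + cfg$n_normals, TRUE, c(0.73, 0.27)),
    matched_normal_id = c(ifelse(seq_len(cfg$n_tumors) <= cfg$n_normals,
                                 nor_id[pmin(seq_len(cfg$n_tumors), cfg$n_normals)],
                                 NA_character_),
                          rep(NA_character_, cfg$n_normals)),
    stringsAsFactors = FALSE
  )

  ## aggressiveness flags follow subtype-specific rates (BRAF-like tumors are
  ## the invasive class; RAS-like intermediate; NBNR indolent)
  lnm_rate <- c("BRAF-like" = 0.37, "RAS-like" = 0.15, "NBNR" = 0)[subtype]
  ete_rate <- c("BRAF-like" = 0.62, "RAS-like" = 0.11, "NBNR" = 0.09)[subtype]
  truth <- list(
    samples = data.frame(sample_id = tum_id, subtype = subtype, driver = driver,
                         lt = lt, oncocytic = oncocytic,
                         lnm = stats::runif(cfg$n_tumors) < lnm_rate,
                         ete = stats::runif(cfg$n_tumors) < ete_rate,
                         stringsAsFactors = FALSE),
    arm_cnv = arm_cnv,
    library_size = lib
  )

  list(counts = expr_matrix(counts, "counts"), annotation = annotation,
       samples = samples, truth = truth, panels = panels, config = cfg)
}

# largest-remainder apportionment of n into named integer counts
.apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

.draw_driver <- function(subtype) {
  switch(subtype,
    "BRAF-like" = sample(c("BRAF", "fusion"), 1, prob = c(0.85, 0.15)),
    "RAS-like" = "H/K/NRAS",
    "NBNR" = sample(c("other-small", "fusion", "driver-unknown"), 1,
                    prob = c(0.5, 0.2, 0.3))
  )
}

.histology_for <- function(subtype) {
  vapply(subtype, function(s) switch(s,
    "BRAF-like" = sample(c("cPTC", "FVPTC-I"), 1, prob = c(0.8, 0.2)),
    "RAS-like" = sample(c("FVPTC-E", "miFTC", "FA"), 1, prob = c(0.4, 0.3, 0.3)),
    "NBNR" = sample(c("FA", "miFTC"), 1, prob = c(0.5, 0.5))), character(1))
}

#' Generate variant and fusion tables from cohort truth
#'
#' Emits one true driver record per tumor whose driver label is not
#' `driver-unknown`, plus decoy records from six classes, each designed to
#' fail exactly one filtration criterion: `high_maf` (population frequency too
#' common), `silent` (consequence filter), `non_driver` (gene not on the
#' driver list), `fusion_low_support` (discordant pairs < 2), `fusion_close`
#' (intra-chromosomal breakpoints < 100 kb apart) and `fusion_in_normal`
#' (candidate also seen in a normal sample).
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param decoy_rates named per-tumor probabilities for the six decoy classes;
#'   missing names default to 0.
#' @param seed integer seed.
#' @return list with data.frames `variants` and `fusions`.
#' @export
generate_alteration_tables <- function(truth,
                                       decoy_rates = c(high_maf = 0.1,
                                                       silent = 0.1,
                                                       non_driver = 0.1,
                                                       fusion_low_support = 0.05,
                                                       fusion_close = 0.05,
                                                       fusion_in_normal = 0.05),
                                       seed = 1L) {
  withr::with_seed(seed, .generate_alterations_impl(truth, decoy_rates))
}

.generate_alterations_impl <- function(truth, decoy_rates) {
  ts <- truth$samples
  rate <- function(k) if (k %in% names(decoy_rates)) decoy_rates[[k]] else 0
  variants <- list(); fusions <- list()
  vrec <- function(sample, gene, hgvs_p, consequence, maf_exac = 0, maf_1kg = 0,
                   maf_esp = 0, in_driver_list = TRUE, class = "true_driver") {
    data.frame(sample = sample, gene = gene, hgvs_p = hgvs_p,
               consequence = consequence, maf_exac = maf_exac,
               maf_1kg = maf_1kg, maf_esp = maf_esp,
               in_driver_list = in_driver_list, class = class,
               stringsAsFactors = FALSE)
  }
  frec <- function(sample, geneA, geneB, chromA, posA, chromB, posB,
                   discordant_pairs, found_in_normal = FALSE,
                   class = "true_driver") {
    data.frame(sample = sample, geneA = geneA, geneB = geneB, chromA = chromA,
               posA = posA, chromB = chromB, posB = posB,
               discordant_pairs = discordant_pairs,
               found_in_normal = found_in_normal, class = class,
               stringsAsFactors = FALSE)
  }
  fusion_partners <- list(
    "BRAF-like" = list(c("CCDC6", "RET"), c("NCOA4", "RET"), c("ETV6", "NTRK3"),
                       c("PICALM", "BRAF")),
    "RAS-like" = list(c("STRN", "ALK")),
    "NBNR" = list(c("PAX8", "PPARG"))
  )
  other_genes <- c("DICER1", "EIF1AX", "IDH1", "PTEN", "SOS1", "SPOP")
  other_hgvs <- c("E1705Q", "R13C", "R132C", "V343E", "N233Y", "P94R")

  for (i in seq_len(nrow(ts))) {
    sid <- ts$sample_id[i]
    drv <- ts$driver[i]
    if (drv == "BRAF") {
      variants[[length(variants) + 1L]] <-
        vrec(sid, "BRAF", "V600E", "nonsynonymous")
    } else if (drv == "H/K/NRAS") {
      variants[[length(variants) + 1L]] <-
        vrec(sid, sample(c("HRAS", "KRAS", "NRAS"), 1), "Q61R", "nonsynonymous")
    } else if (drv == "other-small") {
      k <- sample(length(other_genes), 1)
      variants[[length(variants) + 1L]] <-
        vrec(sid, other_genes[k], other_hgvs[k], "nonsynonymous")
    } else if (drv == "fusion") {
      p <- sample(fusion_partners[[ts$subtype[i]]], 1)[[1]]
      fusions[[length(fusions) + 1L]] <-
        frec(sid, p[1], p[2], "10", 1000000L, "1", 2000000L,
             2L + stats::rpois(1, 8))
    }
    ## decoys, each failing its designed criterion only
    if (stats::runif(1) < rate("high_maf"))
      variants[[length(variants) + 1L]] <-
        vrec(sid, "BRAF", "P403L", "nonsynonymous", maf_exac = 0.01,
             maf_1kg = 0.05, class = "high_maf")
    if (stats::runif(1) < rate("silent"))
      variants[[length(variants) + 1L]] <-
        vrec(sid, "NRAS", "L56L", "silent", class = "silent")
    if (stats::runif(1) < rate("non_driver"))
      variants[[length(variants) + 1L]] <-
        vrec(sid, "OR4F5", "A123T", "nonsynonymous", in_driver_list = FALSE,
             class = "non_driver")
    if (stats::runif(1) < rate("fusion_low_support"))
      fusions[[length(fusions) + 1L]] <-
        frec(sid, "ZNF100", "ZNF200", "19", 500000L, "7", 800000L, 1L,
             class = "fusion_low_support")
    if (stats::runif(1) < rate("fusion_close"))
      fusions[[length(fusions) + 1L]] <-
        frec(sid, "NEIGH1", "NEIGH2", "3", 1000000L, "3", 1050000L,
             2L + stats::rpois(1, 3), class = "fusion_close")
    if (stats::runif(1) < rate("fusion_in_normal"))
      fusions[[length(fusions) + 1L]] <-
        frec(sid, "HK1", "UBC", "10", 1000000L, "12", 5000000L,
             2L + stats::rpois(1, 3), found_in_normal = TRUE,
             class = "fusion_in_normal")
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    cbind(.empty_variants(), class = character())
  fusions <- if (length(fusions)) do.call(rbind, fusions) else
    cbind(.empty_fusions(), class = character())
  list(variants = variants, fusions = fusions)
}

#' Write a synthetic cohort to disk
#'
#' Writes the counts (TSV and MTX triplet), annotation (GTF and BED-like TSV),
#' sample metadata TSV, truth JSON, and — when supplied — variant and fusion
#' TSVs.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory (created if needed).
#' @param alterations optional output of [generate_alteration_tables()].
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, alterations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts_tsv = file.path(dir, "counts.tsv"),
    counts_mtx = file.path(dir, "counts.mtx"),
    annotation_gtf = file.path(dir, "annotation.gtf"),
    annotation_tsv = file.path(dir, "annotation.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_counts(cohort$counts, paths[["counts_tsv"]], "tsv")
  write_counts(cohort$counts, paths[["counts_mtx"]], "mtx")
  write_annotation(cohort$annotation, paths[["annotation_gtf"]], "gtf")
  write_annotation(cohort$annotation, paths[["annotation_tsv"]], "tsv")
  write_metadata(cohort$samples, paths[["samples"]])
  jsonlite::write_json(
    list(samples = cohort$truth$samples,
         arm_cnv = as.data.frame(cohort$truth$arm_cnv),
         library_size = cohort$truth$library_size,
         panels = cohort$panels),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(alterations)) {
    paths <- c(paths, variants = file.path(dir, "variants.tsv"),
               fusions = file.path(dir, "fusions.tsv"))
    data.table::fwrite(alterations$variants, paths[["variants"]], sep = "\t")
    data.table::fwrite(alterations$fusions, paths[["fusions"]], sep = "\t")
  }
  invisible(paths)
}
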