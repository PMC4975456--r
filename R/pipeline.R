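#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates: simulate -> normalize -> signature scores -> molecular
#' subtyping (immunoglobulin panel excluded from the variable-gene universe)
#' -> JRB arm calls -> alteration filtering and driver grouping -> DEG +
#' positional enrichment around the most frequently deleted arm -> cohort
#' contingency report. Every stage logs its name and writes its outputs under
#' `out_dir`; a `manifest.json` with md5 hashes of all outputs makes reruns
#' verifiable. If a stage fails, the error names the stage and earlier
#' outputs persist.
#'
#' @param config a `CohortConfig` from [cohort_config()].
#' @param out_dir output directory.
#' @param decoy_rates passed to [generate_alteration_tables()].
#' @return list with the in-memory stage results (`cohort`, `scores`,
#'   `subtypes`, `arm_calls`, `variants`, `fusions`, `driver_groups`, `deg`,
#'   `enrichment`, `report`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, decoy_rates = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[stage] ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("simulate", {
    co <- generate_cohort(config)
    alt <- if (is.null(decoy_rates)) generate_alteration_tables(co$truth, seed = config$seed)
           else generate_alteration_tables(co$truth, decoy_rates, seed = config$seed)
    write_cohort(co, file.path(out_dir, "inputs"), alterations = alt)
    c(co, list(alterations = alt))
  })
  tumor_ids <- cohort$samples$sample_id[cohort$samples$role == "tumor"]
  normal_ids <- cohort$samples$sample_id[cohort$samples$role == "normal"]

  nl <- stage("normalize", normlog(cohort$counts))
  fk <- stage("fpkm", fpkm(cohort$counts, cohort$annotation))

  scores <- stage("score", {
    tds <- signature_score(nl, gene_panel(cohort$panels$tds, "TDS"), tumor_ids)
    erk <- signature_score(nl, gene_panel(cohort$panels$erk, "ERK"), tumor_ids)
    sc <- rbind(tds, erk)
    data.table::fwrite(sc, file.path(out_dir, "scores.tsv"), sep = "\t")
    sc
  })

  subtypes <- stage("subtype", {
    truth <- cohort$truth$samples
    st <- subtype_cohort(em_subset(nl, samples = tumor_ids),
                         drivers = truth$driver[match(tumor_ids, truth$sample_id)],
                         exclude = cohort$panels$ig, seed = config$seed)
    data.table::fwrite(st$result, file.path(out_dir, "subtypes.tsv"), sep = "\t")
    data.table::fwrite(data.frame(sample_id = rownames(st$embedding),
                                  st$embedding),
                       file.path(out_dir, "embedding.tsv"), sep = "\t")
    st
  })

  arm_calls <- stage("jrb", {
    ac <- jrb_pipeline(fk, cohort$annotation, normal_ids, tumor_ids)
    write_arm_calls(ac, cohort$annotation, file.path(out_dir, "arms.tsv"))
    ac
  })

  filtered <- stage("filter", {
    v <- filter_snv_indel(cohort$alterations$variants)
    f <- filter_fusions(cohort$alterations$fusions)
    data.table::fwrite(v, file.path(out_dir, "variants_filtered.tsv"), sep = "\t")
    data.table::fwrite(f, file.path(out_dir, "fusions_filtered.tsv"), sep = "\t")
    list(variants = v, fusions = f,
         groups = assign_driver_group(tumor_ids, v, f))
  })

  deg_out <- stage("deg", {
    ## validate the most frequently deleted called arm by differential
    ## expression between called carriers and non-carriers
    del_counts <- colSums(arm_calls$calls == "underexpressed", na.rm = TRUE)
    if (max(del_counts) >= 2) {
      arm <- names(which.max(del_counts))
      carriers <- rownames(arm_calls$calls)[arm_calls$calls[, arm] == "underexpressed"]
      others <- setdiff(tumor_ids, carriers)
      deg <- classify_deg(deg_stats(cohort$counts, carriers, others))
      universe <- deg$gene_id
      enr <- positional_enrichment(deg$gene_id[deg$class == "moderate-down"],
                                   cohort$annotation, universe)
      data.table::fwrite(deg, file.path(out_dir, "deg.tsv"), sep = "\t")
      data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
      list(arm = arm, deg = deg, enrichment = enr)
    } else {
      message("no recurrently deleted arm; skipping the DEG validation loop")
      NULL
    }
  })

  report <- stage("report", {
    truth <- cohort$truth$samples
    md <- data.frame(sample_id = tumor_ids,
                     driver_group = unname(filtered$groups[tumor_ids]),
                     lt = truth$lt[match(tumor_ids, truth$sample_id)],
                     age = cohort$samples$age[match(tumor_ids, cohort$samples$sample_id)],
                     stringsAsFactors = FALSE)
    lt_rep <- contingency(md, "driver_group", "lt")
    age_rep <- continuous_compare(md, "driver_group", "age")
    data.table::fwrite(lt_rep$summary, file.path(out_dir, "report_lt.tsv"),
                       sep = "\t")
    data.table::fwrite(age_rep$summary, file.path(out_dir, "report_age.tsv"),
                       sep = "\t")
    list(lt = lt_rep, age = age_rep)
  })

  manifest <- stage("manifest", {
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    mf <- list(seed = config$seed,
               n_tumors = config$n_tumors, n_normals = config$n_normals,
               files = data.frame(path = sub(paste0("^", out_dir, "/?"), "", files),
                                  md5 = unname(tools::md5sum(files)),
                                  stringsAsFactors = FALSE))
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    mf
  })

  list(cohort = cohort, scores = scores, subtypes = subtypes,
       arm_calls = arm_calls, variants = filtered$variants,
       fusions = filtered$fusions, driver_groups = filtered$groups,
       deg = deg_out, report = report, manifest = manifest)
}
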