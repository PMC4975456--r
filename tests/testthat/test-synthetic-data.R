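test_that("the same config yields byte-identical cohorts", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$panels, b$panels)
})

test_that("config validation rejects inconsistent plans", {
  expect_error(small_config(subtype_fractions = c("BRAF-like" = 0.5,
                                                  "RAS-like" = 0.4,
                                                  "NBNR" = 0.2)),
               "sum to 1")
  expect_error(cohort_config(cnv_plan = list(list(arm = "Xq", log2fc = 1,
                                                  carrier_fraction = 0.1))),
               "Xq")
  expect_error(cohort_config(cnv_plan = list(list(arm = "7q", log2fc = 1,
                                                  carrier_fraction = 1.5))),
               "carrier_fraction")
  expect_error(cohort_config(n_tumors = 0), "positive")
})

test_that("with all effects zero, tumors and normals are exchangeable per gene", {
  cfg <- cohort_config(n_tumors = 100, n_normals = 100, n_arms = 10,
                       genes_per_arm = 40,
                       effect_sizes = c(program = 0, erk = 0, tds = 0,
                                        ig = 0, oncocytic = 0),
                       cnv_plan = list(), lt_prob = 0.3, seed = 5)
  co <- generate_cohort(cfg)
  tum <- co$samples$sample_id[co$samples$role == "tumor"]
  nor <- co$samples$sample_id[co$samples$role == "normal"]
  pvals <- apply(co$counts$values, 1, function(x)
    suppressWarnings(stats::ks.test(x[tum], x[nor])$p.value))
  expect_gte(mean(pvals > 0.01), 0.97)
})

test_that("a planted arm dosage is recovered by naive group means", {
  cfg <- cohort_config(n_tumors = 100, n_normals = 20, n_arms = 14,
                       genes_per_arm = 50,
                       effect_sizes = c(program = 0, erk = 0, tds = 0,
                                        ig = 0, oncocytic = 0),
                       lt_prob = 0,
                       cnv_plan = list(list(arm = "7q", log2fc = 1,
                                            carrier_fraction = 0.5)),
                       seed = 21)
  co <- generate_cohort(cfg)
  carriers <- rownames(co$truth$arm_cnv)[co$truth$arm_cnv[, "7q"] > 0]
  others <- setdiff(rownames(co$truth$arm_cnv), carriers)
  nl <- suppressMessages(normlog(co$counts))
  genes7q <- co$annotation$gene_id[co$annotation$arm == "7q"]
  # restrict to well-expressed genes so the +1 pseudocount bias is negligible
  sf <- size_factors(co$counts)
  norm_mean <- rowMeans(sweep(co$counts$values, 2, sf, "/"))
  genes7q <- genes7q[norm_mean[genes7q] >= 50]
  expect_gte(length(genes7q), 20)
  diff <- mean(nl$values[genes7q, carriers]) - mean(nl$values[genes7q, others])
  expect_equal(diff, 1, tolerance = 0.1)
})

test_that("median-of-ratios recovers planted library sizes within 2 percent", {
  # programs on well under 30% of genes, the regime where the median of
  # ratios is an unbiased library-size estimator
  co <- generate_cohort(cohort_config(n_tumors = 40, n_normals = 20, seed = 9,
                                      panel_sizes = c(tds = 8, erk = 10,
                                                      ig = 20, oncocytic = 10,
                                                      program = 30)))
  sf <- size_factors(co$counts)
  lib <- co$truth$library_size[names(sf)]
  rel <- (sf / exp(mean(log(sf)))) / (lib / exp(mean(log(lib))))
  expect_true(all(abs(rel - 1) < 0.02))
})

test_that("alteration tables contain exactly the planted drivers plus designed decoys", {
  co <- generate_cohort(small_config())
  truth <- co$truth

  none <- truth
  none$samples <- truth$samples[0, ]
  empty <- generate_alteration_tables(none, decoy_rates = c(), seed = 1)
  expect_equal(nrow(empty$variants), 0)
  expect_equal(nrow(empty$fusions), 0)

  one <- truth
  one$samples <- data.frame(sample_id = "T1", subtype = "BRAF-like",
                            driver = "BRAF", lt = FALSE, oncocytic = FALSE,
                            lnm = FALSE, ete = FALSE)
  tabs <- generate_alteration_tables(one, decoy_rates = c(), seed = 1)
  expect_equal(nrow(tabs$variants), 1)
  expect_equal(tabs$variants$gene, "BRAF")
  expect_equal(tabs$variants$consequence, "nonsynonymous")
  expect_true(all(tabs$variants[, c("maf_exac", "maf_1kg", "maf_esp")] <=
                    c(1e-4, 0.01, 0.01)))

  n_drivers <- sum(truth$samples$driver != "driver-unknown")
  tabs <- generate_alteration_tables(truth, seed = 2)
  expect_equal(sum(tabs$variants$class == "true_driver") +
                 sum(tabs$fusions$class == "true_driver"), n_drivers)
  expect_true(all(c("high_maf", "silent", "non_driver") %in% tabs$variants$class |
                    nrow(truth$samples) < 20))
})

test_that("decoy counts follow the requested rates", {
  co <- generate_cohort(cohort_config(n_tumors = 200, n_normals = 10,
                                      n_arms = 4, genes_per_arm = 120,
                                      cnv_plan = list(), seed = 3))
  rates <- c(high_maf = 0.2, silent = 0.1, non_driver = 0.15,
             fusion_low_support = 0.1, fusion_close = 0.1,
             fusion_in_normal = 0.1)
  tabs <- generate_alteration_tables(co$truth, rates, seed = 8)
  n <- nrow(co$truth$samples)
  for (cls in names(rates)) {
    found <- sum(tabs$variants$class == cls) + sum(tabs$fusions$class == cls)
    expected <- rates[[cls]] * n
    tol <- 3.5 * sqrt(n * rates[[cls]] * (1 - rates[[cls]]))
    expect_lt(abs(found - expected), tol, label = cls)
  }
})

test_that("driver labels are consistent with planted subtype programs", {
  co <- generate_cohort(cohort_config(seed = 13))
  ts <- co$truth$samples
  expect_true(all(ts$driver[ts$subtype == "BRAF-like"] %in% c("BRAF", "fusion")))
  expect_true(all(ts$driver[ts$subtype == "RAS-like"] == "H/K/NRAS"))
  expect_false(any(ts$driver[ts$subtype == "NBNR"] %in% c("BRAF", "H/K/NRAS")))
  expect_true(all(ts$subtype[ts$oncocytic] == "NBNR"))
  expect_equal(nrow(ts), 180)
})

test_that("write_cohort emits readable files in every dialect", {
  co <- generate_cohort(small_config())
  dir <- withr::local_tempdir()
  alt <- generate_alteration_tables(co$truth, seed = 1)
  paths <- write_cohort(co, dir, alterations = alt)
  m_tsv <- suppressMessages(read_counts(paths[["counts_tsv"]], "tsv"))
  m_mtx <- suppressMessages(read_counts(paths[["counts_mtx"]], "mtx"))
  expect_identical(m_tsv$values, co$counts$values)
  expect_identical(m_mtx$values, co$counts$values)
  ann_gtf <- suppressMessages(read_annotation(paths[["annotation_gtf"]], "gtf"))
  ann_tsv <- suppressMessages(read_annotation(paths[["annotation_tsv"]], "tsv"))
  key <- order(ann_gtf$gene_id)
  expect_equal(ann_gtf[key, c("gene_id", "start", "end", "arm")],
               ann_tsv[order(ann_tsv$gene_id), c("gene_id", "start", "end", "arm")],
               ignore_attr = TRUE)
  md <- suppressMessages(read_metadata(paths[["samples"]]))
  expect_equal(nrow(md), nrow(co$samples))
  v <- suppressMessages(read_variants(paths[["variants"]], "tsv"))
  expect_equal(nrow(v), nrow(alt$variants))
})
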