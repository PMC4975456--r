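test_that("the JRB gene filter applies inclusive expression, biotype and autosome rules", {
  # 10 genes with known means spanning every rule
  v <- matrix(rep(c(2, 1.5, 1.49, 0.2, 3, 5, 1.6, 10, 2, 2), 2), ncol = 2,
              dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  ann <- data.frame(
    gene_id = paste0("g", 1:10),
    chrom = c("1", "1", "1", "2", "X", "chr3", "3", "22", "2", "1"),
    start = c(500L, 100L, 200L, 10L, 5L, 7L, 900L, 1L, 600L, 300L),
    end = c(600L, 200L, 300L, 110L, 105L, 107L, 1000L, 101L, 700L, 400L),
    strand = "+",
    biotype = c(rep("protein_coding", 8), "lincRNA", "protein_coding"),
    length = 100L,
    arm = c("1p", "1p", "1p", "2p", "Xp", "3p", "3q", "22q", "2q", "1q"),
    stringsAsFactors = FALSE
  )
  kept <- jrb_gene_filter(expr_matrix(v, "fpkm"), ann)
  # hand filter: g3 below 1.5, g4 below, gX non-autosomal, g9 non-coding
  # survivors sorted by (chromosome, start): chr1: g2(100) g10(300) g1(500); chr3: g6 g7; chr22: g8
  expect_equal(kept, c("g2", "g10", "g1", "g6", "g7", "g8"))
  expect_true("g2" %in% kept)   # mean exactly 1.5 is kept (inclusive)
  expect_false("g5" %in% kept)  # chrX dropped
  expect_error(jrb_gene_filter(expr_matrix(v * 0, "fpkm"), ann), "no gene")
})

test_that("the normal reference has the closed-form mean and flags zero-sd genes", {
  v <- matrix(c(1, 3,
                2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("n1", "n2")))
  ref <- jrb_reference(expr_matrix(v, "fpkm"), pseudocount = 0)
  expect_equal(unname(ref$mu["g1"]), (log(1) + log(3)) / 2)
  expect_equal(ref$flagged, "g2")
  expect_equal(ref$n_reference, 2)

  withr::with_seed(17, {
    lv <- matrix(rnorm(30 * 200, mean = 2, sd = 0.5), 200, 30,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("n", 1:30)))
  })
  ref2 <- jrb_reference(expr_matrix(exp(lv), "fpkm"), pseudocount = 0)
  # recovered means within a generous simulation CI (se = 0.5/sqrt(30))
  expect_true(all(abs(ref2$mu - 2) < 5 * 0.5 / sqrt(30)))
})

test_that("the two-stage Z transform matches a hand computation and standardizes samples", {
  # 4 genes, 1 tumor; reference mu/sigma chosen by hand
  normals <- matrix(exp(c(0, 1, 0, 2, 1, 3, 2, 4)), nrow = 4, byrow = TRUE,
                    dimnames = list(paste0("g", 1:4), c("n1", "n2")))
  ref <- jrb_reference(expr_matrix(normals, "fpkm"), pseudocount = 0)
  tumor <- matrix(exp(c(2, 3, 1, 5)), 4, 1,
                  dimnames = list(paste0("g", 1:4), "t1"))
  zz <- zz_transform(expr_matrix(tumor, "fpkm"), ref)
  # by hand: mu = (0.5, 1, 2, 3), sigma = sd of each pair
  mu <- c(0.5, 1, 2, 3)
  sig <- apply(matrix(c(0, 1, 0, 2, 1, 3, 2, 4), 4, byrow = TRUE), 1, sd)
  z <- (c(2, 3, 1, 5) - mu) / sig
  expect_equal(unname(zz$zz[, 1]), (z - mean(z)) / sd(z))
  expect_equal(mean(zz$zz[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(zz$zz[, 1]), 1, tolerance = 1e-12)
})

test_that("a tumor equal to the reference mean profile is a degenerate error", {
  normals <- matrix(exp(c(1, 3, 2, 4, 0, 2)), nrow = 3, byrow = TRUE,
                    dimnames = list(paste0("g", 1:3), c("n1", "n2")))
  ref <- jrb_reference(expr_matrix(normals, "fpkm"), pseudocount = 0)
  flat <- matrix(exp(ref$mu), 3, 1, dimnames = list(paste0("g", 1:3), "t1"))
  expect_error(zz_transform(expr_matrix(flat, "fpkm"), ref),
               "zero Z-score dispersion.*t1")
})

test_that("Z-scores are invariant to the logarithm base", {
  m <- random_fpkm(60, 8, seed = 71)
  normal_ids <- paste0("S", 1:4)
  tumor_ids <- paste0("S", 5:8)
  ref <- jrb_reference(em_subset(m, samples = normal_ids), pseudocount = 0.1)
  zz <- zz_transform(em_subset(m, samples = tumor_ids), ref)
  # independent recomputation in log10: the base cancels in (log x - mu)/sigma
  lv10 <- log10(m$values + 0.1)
  mu10 <- rowMeans(lv10[, normal_ids])
  sd10 <- apply(lv10[, normal_ids], 1, sd)
  z10 <- (lv10[, tumor_ids] - mu10) / sd10
  zz10 <- scale(z10)
  expect_equal(unname(zz$zz), unname(zz10[rownames(zz$zz), ]), tolerance = 1e-12)
})

test_that("arm calls center to zero, respect min_genes, and flag a shifted arm", {
  m <- random_fpkm(200, 9, seed = 5)
  ann <- arm_annotation(gene_ids(m), n_arms = 10)
  normal_ids <- paste0("S", 1:4)
  tumor_ids <- paste0("S", 5:9)
  ref <- jrb_reference(em_subset(m, samples = normal_ids))
  zz <- zz_transform(em_subset(m, samples = tumor_ids), ref)

  flat <- zz
  flat$zz[] <- 0.7   # every arm median equal, so centering must zero them all
  calls_flat <- call_arms(flat, ann)
  expect_true(all(calls_flat$values == 0))
  expect_true(all(calls_flat$calls == "neutral"))

  shifted <- zz
  arm1 <- ann$gene_id[ann$arm == "1p"]
  shifted$zz[arm1, "S5"] <- shifted$zz[arm1, "S5"] + 1.2
  calls <- call_arms(shifted, ann)
  expect_equal(unname(calls$calls["S5", "1p"]), "overexpressed")
  expect_true(all(calls$calls["S5", colnames(calls$calls) != "1p"] == "neutral"))

  # per-sample median of callable centered values is exactly zero
  for (s in tumor_ids)
    expect_equal(median(calls$values[s, ], na.rm = TRUE), 0)

  # arms below min_genes are no-call and excluded from centering
  ann_uneven <- ann
  ann_uneven$arm[1:5] <- "6p"
  ann_uneven$chrom[1:5] <- "6"
  sparse <- call_arms(zz, ann_uneven)
  expect_true(all(sparse$calls[, "6p"] == "no-call"))
  expect_true(all(is.na(sparse$values[, "6p"])))
  for (s in tumor_ids)
    expect_equal(median(sparse$values[s, ], na.rm = TRUE), 0)
  expect_error(call_arms(zz, ann, min_genes = 1000), "fewer than 3")
})

test_that("arm calls are invariant to gene order", {
  m <- random_fpkm(150, 8, seed = 33)
  ann <- arm_annotation(gene_ids(m), n_arms = 5)
  perm <- withr::with_seed(1, sample(gene_ids(m)))
  m_perm <- em_subset(m, genes = perm)
  a1 <- jrb_pipeline(m, ann, paste0("S", 1:4), paste0("S", 5:8), min_genes = 5)
  a2 <- jrb_pipeline(m_perm, ann, paste0("S", 1:4), paste0("S", 5:8), min_genes = 5)
  expect_equal(a1$values, a2$values)
  expect_identical(a1$calls, a2$calls)
})

test_that("the full pipeline equals the brute-force implementation elementwise", {
  m <- random_fpkm(200, 10, seed = 83)
  ann <- arm_annotation(gene_ids(m), n_arms = 10)
  normal_ids <- paste0("S", 1:5)
  tumor_ids <- paste0("S", 6:10)
  got <- jrb_pipeline(m, ann, normal_ids, tumor_ids)
  want <- jrb_brute_force(m$values, ann, normal_ids, tumor_ids)
  expect_equal(got$values[, colnames(want$values)], want$values,
               tolerance = 1e-10)
  expect_identical(got$calls[, colnames(want$calls)], want$calls)
})

test_that("arm-call export writes a tidy TSV and whole-arm BED segments", {
  m <- random_fpkm(120, 8, seed = 55)
  ann <- arm_annotation(gene_ids(m), n_arms = 4)
  ac <- jrb_pipeline(m, ann, paste0("S", 1:4), paste0("S", 5:8), min_genes = 5)
  df <- as.data.frame(ac)
  expect_equal(nrow(df), nrow(ac$values) * ncol(ac$values))
  expect_true(all(c("sample", "arm", "centered_value", "call", "n_genes") %in%
                    names(df)))
  path <- file.path(withr::local_tempdir(), "arms.tsv")
  out <- write_arm_calls(ac, ann, path)
  expect_true(file.exists(out[["tsv"]]))
  expect_true(file.exists(out[["bed"]]))
})
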