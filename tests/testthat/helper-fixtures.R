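# shared fixtures and independent oracles

invisible(stats::runif(1))  # initialize .Random.seed so withr can restore it

tiny_counts <- function() {
  m <- matrix(c(0, 1, 3,
                10, 20, 30), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  expr_matrix(m, "counts")
}

small_config <- function(...) {
  cohort_config(n_tumors = 30, n_normals = 15, n_arms = 10, genes_per_arm = 30,
                panel_sizes = c(tds = 4, erk = 6, ig = 8, oncocytic = 6,
                                program = 10),
                cnv_plan = list(), seed = 42, ...)
}

# random FPKM-like matrix for JRB fixtures
random_fpkm <- function(n_genes, n_samples, seed, prefix = "S") {
  withr::with_seed(seed, {
    v <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 2, sdlog = 1),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                paste0(prefix, seq_len(n_samples))))
    expr_matrix(v, "fpkm")
  })
}

arm_annotation <- function(gene_ids, n_arms, chrom_offset = 0) {
  arms <- thyrotype::arm_names(n_arms)
  per <- ceiling(length(gene_ids) / n_arms)
  arm <- rep(arms, each = per)[seq_along(gene_ids)]
  data.frame(gene_id = gene_ids, chrom = sub("[pq]$", "", arm),
             start = seq_along(gene_ids) * 1000L,
             end = seq_along(gene_ids) * 1000L + 500L,
             strand = "+", biotype = "protein_coding",
             length = 500L, arm = arm, stringsAsFactors = FALSE)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more probable
# than the observed one
fisher2x2_enum <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, spelled out
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# brute-force JRB pipeline, written independently of the package internals:
# scalar loops, explicit formulas, log10 (the base must cancel)
jrb_brute_force <- function(fpkm_mat, ann, normal_ids, tumor_ids,
                            min_mean_fpkm = 1.5, pseudo = 0.1,
                            min_genes = 10, threshold = 0.5) {
  keep <- character(0)
  for (g in rownames(fpkm_mat)) {
    row <- ann[ann$gene_id == g, ]
    auto <- sub("^chr", "", row$chrom) %in% as.character(1:22)
    if (auto && row$biotype == "protein_coding" &&
        mean(fpkm_mat[g, ]) >= min_mean_fpkm)
      keep <- c(keep, g)
  }
  ord <- order(as.integer(sub("^chr", "", ann$chrom[match(keep, ann$gene_id)])),
               ann$start[match(keep, ann$gene_id)])
  keep <- keep[ord]
  mu <- sig <- setNames(numeric(length(keep)), keep)
  for (g in keep) {
    lv <- log10(fpkm_mat[g, normal_ids] + pseudo)
    mu[g] <- mean(lv)
    sig[g] <- sd(lv)
  }
  keep <- keep[sig[keep] > 0]
  z <- matrix(NA_real_, length(keep), length(tumor_ids),
              dimnames = list(keep, tumor_ids))
  for (g in keep) for (s in tumor_ids)
    z[g, s] <- (log10(fpkm_mat[g, s] + pseudo) - mu[g]) / sig[g]
  zz <- z
  for (s in tumor_ids) zz[, s] <- (z[, s] - mean(z[, s])) / sd(z[, s])
  arm_of <- ann$arm[match(keep, ann$gene_id)]
  arms <- sort(unique(arm_of))
  callable <- arms[vapply(arms, function(a) sum(arm_of == a), 0L) >= min_genes]
  values <- matrix(NA_real_, length(tumor_ids), length(arms),
                   dimnames = list(tumor_ids, arms))
  calls <- matrix("no-call", length(tumor_ids), length(arms),
                  dimnames = list(tumor_ids, arms))
  for (s in tumor_ids) {
    med <- setNames(rep(NA_real_, length(arms)), arms)
    for (a in callable) med[a] <- median(zz[arm_of == a, s])
    cen <- med - median(med[callable])
    values[s, ] <- cen
    for (a in callable) {
      calls[s, a] <- if (cen[a] >= threshold) "overexpressed"
        else if (cen[a] <= -threshold) "underexpressed" else "neutral"
    }
  }
  list(values = values, calls = calls)
}
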