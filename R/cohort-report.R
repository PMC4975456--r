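#' Round half-up
#'
#' Decimal rounding where ties go away from zero (the convention of printed
#' clinical tables), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with table-style rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `digits` decimals.
#'
#' @param numerator,denominator counts.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
percentage <- function(numerator, denominator, digits = 2) {
  round_half_up(100 * numerator / denominator, digits)
}

#' Contingency report for a categorical variable across driver groups
#'
#' Per-group numerator/denominator and percentage (half-up, 2 decimals) of a
#' binary variable, an omnibus association test — Pearson's chi-square, or
#' Fisher's exact test when any expected cell count is below 5 — and pairwise
#' post-hoc tests with Bonferroni correction (p times the number of pairs,
#' capped at 1).
#'
#' @param metadata data.frame of per-sample covariates.
#' @param group name of the grouping column (e.g. driver group).
#' @param variable name of a logical/binary column.
#' @return a `ContingencyReport` list: `summary` (group, n, denominator,
#'   percent), `test`, `p`, `posthoc` (pairwise Bonferroni-adjusted p's),
#'   `m` (number of pairwise comparisons).
#' @export
contingency <- function(metadata, group, variable) {
  g <- metadata[[group]]
  x <- metadata[[variable]]
  keep <- !is.na(g) & !is.na(x)
  g <- g[keep]; x <- as.logical(x[keep])
  if (!is.factor(g)) g <- factor(g)
  empty <- levels(g)[tabulate(g, nbins = nlevels(g)) == 0]
  if (length(empty)) {
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  tab <- table(group = g, value = factor(x, c(FALSE, TRUE)))
  summary <- data.frame(
    group = rownames(tab),
    n = as.integer(tab[, "TRUE"]),
    denominator = as.integer(rowSums(tab)),
    stringsAsFactors = FALSE
  )
  summary$percent <- percentage(summary$n, summary$denominator)
  omni <- .assoc_test(tab)
  pairs <- utils::combn(rownames(tab), 2, simplify = FALSE)
  m <- length(pairs)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    sub <- tab[pr, , drop = FALSE]
    res <- .assoc_test(sub)
    data.frame(group1 = pr[1], group2 = pr[2], test = res$test,
               p_raw = res$p, p_bonferroni = min(1, res$p * m),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, test = omni$test, p = omni$p,
                 posthoc = posthoc, m = m, variable = variable),
            class = "ContingencyReport")
}

# chi-square unless any expected count < 5, then Fisher; degenerate tables
# (a single row or column) carry no association to test
.assoc_test <- function(tab) {
  if (nrow(tab) < 2 || sum(colSums(tab) > 0) < 2)
    return(list(test = "none", p = NA_real_))
  expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
  if (any(expected < 5))
    list(test = "Fisher", p = stats::fisher.test(tab)$p.value)
  else
    list(test = "chi-square",
         p = stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' @export
print.ContingencyReport <- function(x, ...) {
  cat(sprintf("ContingencyReport: %s\n", x$variable))
  print(x$summary, row.names = FALSE)
  cat(sprintf("omnibus %s p = %.4g; %d pairwise comparisons (Bonferroni)\n",
              x$test, x$p, x$m))
  invisible(x)
}

#' Compare a continuous variable across groups
#'
#' Group means and standard deviations, an omnibus test (Welch t-test for two
#' groups, one-way ANOVA otherwise) and pairwise Welch t-tests with Bonferroni
#' correction.
#'
#' @param metadata data.frame of per-sample covariates.
#' @param group name of the grouping column.
#' @param variable name of a numeric column.
#' @return list with `summary` (group, n, mean, sd), `test`, `p`, `posthoc`.
#' @export
continuous_compare <- function(metadata, group, variable) {
  g <- metadata[[group]]
  x <- metadata[[variable]]
  keep <- !is.na(g) & !is.na(x)
  g <- factor(g[keep]); x <- as.numeric(x[keep])
  smry <- do.call(rbind, lapply(levels(g), function(lv) {
    xi <- x[g == lv]
    data.frame(group = lv, n = length(xi), mean = mean(xi), sd = stats::sd(xi),
               stringsAsFactors = FALSE)
  }))
  if (nlevels(g) == 2) {
    test <- "t-test"
    p <- stats::t.test(x ~ g)$p.value
  } else {
    test <- "ANOVA"
    p <- summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1]
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(pairs)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    pv <- stats::t.test(x[g == pr[1]], x[g == pr[2]])$p.value
    data.frame(group1 = pr[1], group2 = pr[2], p_raw = pv,
               p_bonferroni = min(1, pv * m), stringsAsFactors = FALSE)
  }))
  list(summary = smry, test = test, p = p, posthoc = posthoc, m = m)
}
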