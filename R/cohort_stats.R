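# The statistical comparison layer: Kruskal-Wallis with Benjamini-Hochberg
# correction across a variable family, two-sided Mann-Whitney, Fisher /
# chi-square proportion tests, correlation matrices with significance
# masking, and differential expression by log2 fold-change.

#' Kruskal-Wallis tests with BH correction across a variable family
#'
#' Runs a tie-corrected Kruskal-Wallis test for each variable (row of
#' `values`) against the group labels, then applies Benjamini-Hochberg
#' correction across exactly the family of variables passed in this call
#' (families from different analyses are never pooled).
#'
#' @param values numeric matrix (variables x samples) or a single named
#'   numeric vector treated as one variable.
#' @param groups character/factor vector of group labels per sample.
#' @return data.frame with `variable`, `statistic`, `raw_p`, `adj_p`, and
#'   one `median_<group>` column per group.
#' @export
kruskal_bh <- function(values, groups) {
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, nrow = 1, dimnames = list("value", names(values)))
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    abort("groups must have one label per sample (column of values)")
  }
  tab <- table(groups)
  if (length(tab) < 2) abort("need >= 2 groups")
  if (any(tab < 2)) {
    abort("group(s) with < 2 observations: ",
          paste(names(tab)[tab < 2], collapse = ", "))
  }
  gf <- factor(groups)
  res <- lapply(seq_len(nrow(values)), function(i) {
    kt <- stats::kruskal.test(values[i, ], gf)
    meds <- tapply(values[i, ], gf, stats::median)
    c(statistic = unname(kt$statistic), raw_p = kt$p.value, meds)
  })
  res <- do.call(rbind, res)
  out <- data.frame(variable = rownames(values),
                    statistic = res[, "statistic"],
                    raw_p = res[, "raw_p"],
                    adj_p = stats::p.adjust(res[, "raw_p"], method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in levels(gf)) out[[paste0("median_", g)]] <- res[, g]
  out
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value when the combined sample size is at most 20 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param a,b numeric vectors (each with >= 2 observations).
#' @return list with `statistic` (U) and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each side needs >= 2 observations")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Proportion test for a 2 x k count table
#'
#' Fisher's exact test for 2 x 2 tables with any expected cell at or below
#' 5; Pearson chi-square (no continuity correction) otherwise.
#'
#' @param table non-negative integer matrix, 2 x k.
#' @return list with `method` ("fisher" or "chisq") and `p_value`.
#' @export
proportion_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero-margin table")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == c(2, 2)) && any(expected <= 5)) {
    list(method = "fisher", p_value = stats::fisher.test(table)$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(method = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  }
}

#' Pairwise correlation matrix with significance mask
#'
#' Correlates every column of `x` with every column of `y` (default `y =
#' x`) using Spearman rank or Pearson correlation on pairwise-complete
#' observations. The mask is TRUE where the correlation is NOT significant
#' at `alpha` (the convention for crossing out cells in a heat map). Pairs
#' with fewer than 4 complete observations are recorded as NA with a
#' warning.
#'
#' @param x,y numeric matrices or data.frames, samples x variables.
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha significance level for the mask.
#' @return list of class `correlation_matrix` with `rho`, `p`, `mask`,
#'   `method`, `alpha`.
#' @export
correlation_matrix <- function(x, y = NULL, method = c("spearman", "pearson"),
                               alpha = 0.05) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (is.null(y)) y <- x
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("x and y must cover identical samples")
  rho <- p <- matrix(NA_real_, ncol(x), ncol(y),
                     dimnames = list(colnames(x), colnames(y)))
  few <- FALSE
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(y))) {
      ok <- is.finite(x[, i]) & is.finite(y[, j])
      if (sum(ok) < 4) { few <- TRUE; next }
      ct <- suppressWarnings(stats::cor.test(x[ok, i], y[ok, j],
                                             method = method, exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  if (few) warning("pair(s) with < 4 complete observations recorded as NA")
  structure(list(rho = rho, p = p, mask = p > alpha, method = method,
                 alpha = alpha), class = "correlation_matrix")
}

#' Differential expression by log2 fold-change
#'
#' For every gene, `log2fc = log2(mean_a + pseudocount) - log2(mean_b +
#' pseudocount)` on TPM group means, with a per-gene two-sided Mann-Whitney
#' p-value (normal approximation with tie correction) and BH adjustment
#' across all genes. Genes with `adj_p < alpha` are flagged significant.
#' Set `test = "welch"` for a Welch t-test on log2(TPM + 1) instead.
#'
#' @param expr genes x samples TPM matrix.
#' @param manifest cohort manifest.
#' @param group_a,group_b group labels to contrast (log2fc is a vs b).
#' @param pseudocount added to group means before log2.
#' @param alpha adjusted-p significance threshold.
#' @param test `"mann_whitney"` or `"welch"`.
#' @return data.frame with `gene`, `log2fc`, `raw_p`, `adj_p`,
#'   `significant`.
#' @export
deg <- function(expr, manifest, group_a, group_b, pseudocount = 1,
                alpha = 0.05, test = c("mann_whitney", "welch")) {
  test <- match.arg(test)
  ids_a <- intersect(colnames(expr), manifest$sample_id[manifest$group == group_a])
  ids_b <- intersect(colnames(expr), manifest$sample_id[manifest$group == group_b])
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort("both contrast groups must be non-empty in the expression matrix")
  }
  a <- expr[, ids_a, drop = FALSE]
  b <- expr[, ids_b, drop = FALSE]
  log2fc <- log2(rowMeans(a) + pseudocount) - log2(rowMeans(b) + pseudocount)
  raw_p <- vapply(seq_len(nrow(expr)), function(i) {
    if (test == "mann_whitney") {
      stats::wilcox.test(a[i, ], b[i, ], exact = FALSE, correct = TRUE)$p.value
    } else {
      stats::t.test(log2(a[i, ] + 1), log2(b[i, ] + 1))$p.value
    }
  }, numeric(1))
  adj_p <- stats::p.adjust(raw_p, method = "BH")
  data.frame(gene = rownames(expr), log2fc = log2fc, raw_p = raw_p,
             adj_p = adj_p, significant = adj_p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
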