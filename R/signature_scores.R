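# Cohort-level z-score machinery and the composite transcriptomic scores
# and classification rules: interferon-gamma score, T cell-inflamed
# three-way classification, T cell dysfunction score, STING score, and the
# non-functional CD8 rule.

#' Cohort z-scores of an expression matrix
#'
#' Standardizes each gene across samples: subtract the cohort mean, divide
#' by the cohort SD. The SD is the population SD (divide by n) by default;
#' set `sd_type = "sample"` for the n-1 denominator. Genes with zero
#' variance map to an all-zero row with a warning. An optional `log2p1`
#' transform is applied per cell before standardization.
#'
#' @param expr genes x samples numeric matrix (TPM).
#' @param transform `"none"` or `"log2p1"` (log2(TPM + 1)).
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return genes x samples matrix of z-scores.
#' @export
cohort_zscores <- function(expr, transform = c("none", "log2p1"),
                           sd_type = c("population", "sample")) {
  transform <- match.arg(transform)
  sd_type <- match.arg(sd_type)
  if (ncol(expr) < 2) abort("z-scores need >= 2 samples (SD undefined)")
  x <- if (transform == "log2p1") log2(expr + 1) else expr
  mu <- rowMeans(x)
  n <- ncol(x)
  ss <- rowSums((x - mu)^2)
  sdv <- sqrt(ss / if (sd_type == "population") n else n - 1)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) mapped to all-zero z-scores: ",
            paste(utils::head(rownames(x)[zero], 5), collapse = ", "))
    sdv[zero] <- 1
  }
  (x - mu) / sdv
}

require_genes <- function(expr, genes, what) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    abort(what, ": gene(s) absent from expression matrix: ",
          paste(missing, collapse = ", "))
  }
  invisible(genes)
}

#' Generic composite signature score
#'
#' Scores each sample on a gene set by aggregating per-gene cohort
#' z-scores: `mean_z` (mean over present set genes, robust to partial
#' membership) or `sum_z` (sum over required set genes).
#'
#' @param expr genes x samples TPM matrix.
#' @param genes character vector of set gene symbols.
#' @param aggregation `"mean_z"` or `"sum_z"`.
#' @param transform passed to [cohort_zscores()].
#' @param require_all if TRUE, error when any set gene is absent; if FALSE,
#'   score over the present subset (error only when none present).
#' @param sd_type passed to [cohort_zscores()].
#' @return named numeric vector, one score per sample.
#' @export
signature_score <- function(expr, genes,
                            aggregation = c("mean_z", "sum_z"),
                            transform = c("none", "log2p1"),
                            require_all = FALSE,
                            sd_type = c("population", "sample")) {
  aggregation <- match.arg(aggregation)
  transform <- match.arg(transform)
  sd_type <- match.arg(sd_type)
  genes <- unique(trimws(genes))
  present <- intersect(genes, rownames(expr))
  if (require_all) {
    require_genes(expr, genes, "signature_score")
  } else if (length(present) == 0) {
    abort("signature_score: none of the ", length(genes),
          " signature genes present in the expression matrix")
  } else if (length(present) < length(genes)) {
    message("signature_score: ", length(present), "/", length(genes),
            " signature genes present")
  }
  z <- cohort_zscores(expr[present, , drop = FALSE], transform = transform,
                      sd_type = sd_type)
  if (aggregation == "mean_z") colMeans(z) else colSums(z)
}

#' T cell dysfunction score
#'
#' Sum of cohort z-scores of HAVCR2 (TIM3), LAG3, and PDCD1 (PD-1) mRNA
#' levels. All three genes must be present.
#'
#' @param expr genes x samples TPM matrix.
#' @param transform passed to [cohort_zscores()]; raw TPM by default.
#' @return named numeric vector, one score per sample.
#' @export
dysfunction_score <- function(expr, transform = "none") {
  genes <- c("HAVCR2", "LAG3", "PDCD1")
  require_genes(expr, genes, "dysfunction_score")
  signature_score(expr, genes, aggregation = "sum_z", transform = transform,
                  require_all = TRUE)
}

#' Composite STING pathway score
#'
#' Sum of cohort z-scores of the key cGAS-STING pathway regulators TMEM173
#' (STING), CGAS, CCL5, CXCL10, and IRF3, aggregated in parallel to
#' [dysfunction_score()]; set `aggregation = "mean_z"` for the mean variant.
#'
#' @param expr genes x samples TPM matrix.
#' @param aggregation `"sum_z"` (default) or `"mean_z"`.
#' @param transform passed to [cohort_zscores()].
#' @return named numeric vector, one score per sample.
#' @export
sting_score <- function(expr, aggregation = "sum_z", transform = "none") {
  genes <- c("TMEM173", "CGAS", "CCL5", "CXCL10", "IRF3")
  require_genes(expr, genes, "sting_score")
  signature_score(expr, genes, aggregation = aggregation,
                  transform = transform, require_all = TRUE)
}

#' Interferon-gamma signature score
#'
#' Mean of per-gene cohort z-scores of log2(TPM + 1) over the present
#' signature genes. The default membership ([builtin_genesets()]`$ifng`)
#' follows the 6-gene anti-PD-1 response signature; any gene set (e.g. from
#' a GMT file) can be supplied.
#'
#' @param expr genes x samples TPM matrix.
#' @param genes signature gene symbols.
#' @return named numeric vector, one score per sample.
#' @export
ifng_score <- function(expr, genes = builtin_genesets()$ifng) {
  signature_score(expr, genes, aggregation = "mean_z",
                  transform = "log2p1", require_all = FALSE)
}

#' Three-way T cell-inflamed signature classification
#'
#' Scores samples on a T cell-inflamed gene set (mean z of log2(TPM + 1))
#' and classifies with two thresholds: score < `t_low` is `TIS_neg`, score
#' > `t_high` is `TIS_pos`, everything between (both comparisons strict) is
#' `undetermined`. Default thresholds are the cohort score tertiles, so a
#' cohort with distinct scores splits into three near-equal classes.
#'
#' @param expr genes x samples TPM matrix.
#' @param genes signature gene symbols (default the 18-gene T cell-inflamed
#'   set from [builtin_genesets()]).
#' @param thresholds numeric length-2 `c(t_low, t_high)` with
#'   `t_low < t_high`, or NULL for cohort tertiles.
#' @return list with `score` (named numeric) and `class` (named factor with
#'   levels TIS_neg, undetermined, TIS_pos).
#' @export
tis_classify <- function(expr, genes = builtin_genesets()$tis,
                         thresholds = NULL) {
  score <- signature_score(expr, genes, aggregation = "mean_z",
                           transform = "log2p1", require_all = FALSE)
  if (is.null(thresholds)) {
    # cohort tertiles; ties may collapse them, in which case the strict
    # comparisons below classify the tied mass as undetermined
    thresholds <- unname(stats::quantile(score, c(1, 2) / 3))
  } else if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
    abort("configuration error: thresholds must satisfy t_low < t_high")
  }
  cls <- rep("undetermined", length(score))
  cls[score < thresholds[1]] <- "TIS_neg"
  cls[score > thresholds[2]] <- "TIS_pos"
  list(score = score,
       class = stats::setNames(
         factor(cls, levels = c("TIS_neg", "undetermined", "TIS_pos")),
         names(score)),
       thresholds = thresholds)
}

#' Non-functional CD8 T cell classification
#'
#' Flags samples whose transcriptome indicates dysfunctional CD8 T cells:
#' dysfunction score strictly greater than `cutoff` (default 1.0) combined
#' with FGFBP2 mRNA strictly below the whole-cohort median. Samples with
#' zero CD8 fraction are excluded (`eligible = FALSE`) from the denominator
#' of any reported percentage, since the rule is defined among tumors with
#' non-zero CD8 infiltration.
#'
#' @param dysfunction per-sample dysfunction scores.
#' @param fgfbp2_tpm per-sample FGFBP2 TPM (median taken over all samples).
#' @param cd8_fraction per-sample CD8 T cell fraction.
#' @param cutoff dysfunction threshold (strict >).
#' @return data.frame with `sample_id`, `nonfunctional` (logical), and
#'   `eligible` (logical; FALSE where `cd8_fraction == 0`).
#' @export
nonfunctional_cd8_classify <- function(dysfunction, fgfbp2_tpm, cd8_fraction,
                                       cutoff = 1.0) {
  n <- length(dysfunction)
  if (n == 0) abort("empty cohort")
  if (length(fgfbp2_tpm) != n || length(cd8_fraction) != n) {
    abort("dysfunction, fgfbp2_tpm, and cd8_fraction must cover identical samples")
  }
  ids <- names(dysfunction)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  med <- stats::median(fgfbp2_tpm)
  data.frame(sample_id = ids,
             nonfunctional = dysfunction > cutoff & fgfbp2_tpm < med,
             eligible = cd8_fraction > 0,
             stringsAsFactors = FALSE)
}
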