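# Gene-set enrichment: the weighted Kolmogorov-Smirnov running-sum
# enrichment score, preranked GSEA with a gene-permutation null, and
# single-sample GSEA (ssGSEA) with rank-position weighting.

# sort a named ranking metric descending, ties broken by gene symbol
# (deterministic, stable)
sort_ranked <- function(metric) {
  if (is.null(names(metric))) abort("ranking metric must be a named vector")
  if (anyDuplicated(names(metric))) abort("duplicate genes in ranked list")
  if (any(!is.finite(metric))) abort("ranking metric must be finite")
  metric[order(-metric, names(metric), method = "radix")]
}

# signed maximum deviation of the running sum for hit positions `idx`
# (sorted increasing) in a universe of size N with hit weights `w`
es_from_positions <- function(idx, w, N) {
  m <- length(idx)
  total <- sum(w)
  if (total == 0) { w <- rep(1, m); total <- m }
  phit <- cumsum(w) / total
  k <- seq_len(m)
  pmiss <- (idx - k) / (N - m)      # P_miss both just before and after hit k
  dev <- c(phit - pmiss,            # deviation just after each hit
           c(0, phit[-m]) - pmiss)  # deviation just before each hit
  best_pos <- max(dev, 0)
  best_neg <- min(dev, 0)
  # exact magnitude ties resolve to the positive deviation
  if (best_pos >= -best_neg) unname(best_pos) else unname(best_neg)
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: walking the ranked
#' list from top to bottom, set members ("hits") increment the sum by
#' `|metric|^alpha / sum_set |metric|^alpha` and non-members decrement by
#' `1 / (N - N_set)`; the enrichment score is the signed maximum deviation
#' from zero. With `alpha = 0` the statistic depends on ranks only and lies
#' in `[-1, 1]`.
#'
#' @param metric named numeric ranking metric (any order; sorted descending
#'   internally, ties broken by gene symbol).
#' @param geneset character vector of set gene symbols.
#' @param alpha non-negative rank weighting exponent.
#' @return the enrichment score (scalar).
#' @export
es <- function(metric, geneset, alpha = 1) {
  ranked <- sort_ranked(metric)
  N <- length(ranked)
  idx <- which(names(ranked) %in% geneset)
  if (length(idx) == 0) abort("no gene of the set is present in the ranked list")
  if (length(idx) == N) abort("gene set covers the entire universe")
  es_from_positions(idx, abs(ranked[idx])^alpha, N)
}

#' Preranked GSEA with a gene-permutation null
#'
#' For each gene set, computes the enrichment score of the observed ranking
#' and a null distribution by drawing `nperm` random gene sets of the same
#' size from the universe (gene-label permutation, preserving set size).
#' The normalized enrichment score is `ES / mean(|null ES| of matching
#' sign)`; the p-value is the sign-stratified empirical tail probability
#' with +1 smoothing. Two FDR columns are reported: `fdr` is
#' Benjamini-Hochberg over the empirical p-values (the default), and
#' `fdr_nes` is the classic sign-stratified NES null-ratio estimate.
#'
#' @param metric named numeric ranking metric.
#' @param genesets named list of gene symbol vectors.
#' @param nperm number of permutations (>= 100).
#' @param alpha rank weighting exponent.
#' @param seed RNG seed; results are deterministic given the seed.
#' @return data.frame with `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `fdr_nes`, ordered as the input sets.
#' @export
preranked_gsea <- function(metric, genesets, nperm = 1000, alpha = 1,
                           seed = 1) {
  if (length(genesets) == 0) abort("empty gene set list")
  if (nperm < 100) abort("nperm must be >= 100")
  ranked <- sort_ranked(metric)
  N <- length(ranked)
  wts <- abs(ranked)^alpha
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sizes <- vapply(genesets, function(g)
    sum(names(ranked) %in% g), integer(1))
  if (any(sizes == 0)) {
    abort("gene set(s) with no member in the ranked list: ",
          paste(names(genesets)[sizes == 0], collapse = ", "))
  }
  if (any(sizes == N)) abort("gene set covers the entire universe")

  es_obs <- vapply(seq_along(genesets), function(i) {
    idx <- which(names(ranked) %in% genesets[[i]])
    es_from_positions(idx, wts[idx], N)
  }, numeric(1))

  null_by_size <- lapply(unique(sizes), function(m) {
    vapply(seq_len(nperm), function(b) {
      idx <- sort.int(sample.int(N, m))
      es_from_positions(idx, wts[idx], N)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(unique(sizes))

  nes <- p <- numeric(length(genesets))
  nes_null_all <- list()
  for (i in seq_along(genesets)) {
    null <- null_by_size[[as.character(sizes[i])]]
    same <- if (es_obs[i] >= 0) null[null >= 0] else null[null < 0]
    if (length(same) == 0) {
      nes[i] <- NA_real_; p[i] <- 1 / (1 + 0)
    } else {
      nes[i] <- es_obs[i] / mean(abs(same))
      p[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
    }
    pos <- null[null >= 0]; neg <- null[null < 0]
    nes_null_all[[i]] <- c(if (length(pos) > 0) pos / mean(pos),
                           if (length(neg) > 0) neg / abs(mean(neg)))
  }

  # classic NES-ratio FDR, sign-stratified
  all_null_nes <- unlist(nes_null_all)
  fdr_nes <- vapply(seq_along(genesets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(all_null_nes >= nes[i])
      den <- mean(nes >= nes[i], na.rm = TRUE)
    } else {
      num <- mean(all_null_nes <= nes[i])
      den <- mean(nes <= nes[i], na.rm = TRUE)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set = names(genesets), size = sizes, es = es_obs, nes = nes,
             p = p, fdr = stats::p.adjust(p, method = "BH"),
             fdr_nes = fdr_nes, row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-sample GSEA
#'
#' For each sample, genes are ranked by expression (descending, ties broken
#' by symbol) and each gene at position `j` of `N` receives rank weight
#' `(N - j + 1)^alpha`. The score for a (sample, set) pair is the sum over
#' all positions of the difference between the weighted hit ECDF and the
#' unweighted miss ECDF. Depends on within-sample ranks only, so it is
#' invariant to monotone transforms of a sample's expression.
#'
#' @param expr genes x samples matrix.
#' @param genesets named list of gene symbol vectors.
#' @param alpha rank weighting exponent (0.25 by the usual ssGSEA
#'   convention).
#' @return samples x sets numeric score matrix; sets with no gene present
#'   give NA with a warning.
#' @export
ssgsea <- function(expr, genesets, alpha = 0.25) {
  if (length(genesets) == 0) abort("empty gene set list")
  genes <- rownames(expr)
  N <- length(genes)
  member <- lapply(genesets, function(g) genes %in% g)
  n_present <- vapply(member, sum, integer(1))
  if (any(n_present == 0)) {
    warning("gene set(s) with no member present, scored as NA: ",
            paste(names(genesets)[n_present == 0], collapse = ", "))
  }
  if (any(n_present == N)) abort("gene set covers the entire universe")
  out <- matrix(NA_real_, ncol(expr), length(genesets),
                dimnames = list(colnames(expr), names(genesets)))
  rank_w <- (N:1)^alpha
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes, method = "radix")
    for (k in seq_along(genesets)) {
      m <- n_present[k]
      if (m == 0) next
      hit <- member[[k]][ord]
      w <- ifelse(hit, rank_w, 0)
      phit <- cumsum(w) / sum(w)
      pmiss <- cumsum(!hit) / (N - m)
      out[j, k] <- sum(phit - pmiss)
    }
  }
  out
}

#' Range-normalize an ssGSEA score matrix
#'
#' Rescales scores by the global range (max - min) of the matrix, the usual
#' ssGSEA normalization.
#'
#' @param scores samples x sets matrix from [ssgsea()].
#' @return matrix of the same shape.
#' @export
ssgsea_normalize <- function(scores) {
  rng <- range(scores, na.rm = TRUE)
  scores / (rng[2] - rng[1])
}
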