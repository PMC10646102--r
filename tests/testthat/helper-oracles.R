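# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive each statistic from its
# definition, staying independent of the implementation paths they check.

# genes x samples matrix with deterministic pseudo-random TPM values
make_expr <- function(n_genes, n_samples, seed = 1, genes = NULL) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 2, sdlog = 1),
              n_genes, n_samples)
  rownames(m) <- if (is.null(genes)) sprintf("G%03d", seq_len(n_genes)) else genes
  colnames(m) <- sprintf("S%03d", seq_len(n_samples))
  m
}

# literal Benjamini-Hochberg step-up: sort p ascending, adj_i =
# min_{j >= i} ( p_(j) * n / j ), capped at 1, mapped back to input order
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# literal running-sum GSEA enrichment score: walk every position
es_bruteforce <- function(metric, geneset, alpha = 0) {
  ord <- order(-metric, names(metric), method = "radix")
  ranked <- metric[ord]
  hit <- names(ranked) %in% geneset
  N <- length(ranked)
  w <- abs(ranked)^alpha
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) unname(w[i]) / sum(w) else -1 / (N - sum(hit))
    hi <- max(hi, run)
    lo <- min(lo, run)
  }
  if (hi >= -lo) hi else lo   # positive deviation wins exact ties
}

# literal per-position ssGSEA sum of weighted hit ECDF minus miss ECDF
ssgsea_bruteforce <- function(values, geneset, alpha = 0.25) {
  ord <- order(-values, names(values), method = "radix")
  hit <- names(values)[ord] %in% geneset
  N <- length(values)
  w <- (N:1)^alpha
  phit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  pmiss <- cumsum(!hit) / (N - sum(hit))
  sum(phit - pmiss)
}

# Spearman rho via the no-ties sum-of-squared-rank-differences formula
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (with fixed margins) no more
# probable than the observed one
fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# mutation record builder
mut_rec <- function(sample_id, gene = "BRAF", variant_class = "missense",
                    pathogenicity = "pathogenic", germline_flagged = FALSE) {
  data.frame(sample_id = sample_id, gene = gene,
             variant_class = variant_class, pathogenicity = pathogenicity,
             germline_flagged = germline_flagged, stringsAsFactors = FALSE)
}

# a small fast generator configuration for module tests
small_config <- function(seed = 1, n = c(PCM = 20, MBM = 20, ECM = 20), ...) {
  generator_config(n_per_group = n, n_genes = 400, seed = seed, ...)
}
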