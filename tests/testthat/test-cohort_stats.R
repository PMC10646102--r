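# The statistical comparison layer against brute-force oracles.

test_that("Kruskal-Wallis: identical groups give H = 0, p = 1", {
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("PCM", "MBM", "ECM"), each = 4)
  res <- kruskal_bh(v, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$raw_p, 1, tolerance = 1e-12)
  expect_error(kruskal_bh(v[1:5], c("a", "a", "a", "a", "b")), "< 2")
})

test_that("two-group Kruskal-Wallis orders p like the rank-sum test", {
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12)
  small_shift <- kruskal_bh(c(a, b + 0.3), rep(c("x", "y"), each = 12))
  large_shift <- kruskal_bh(c(a, b + 3.0), rep(c("x", "y"), each = 12))
  expect_lt(large_shift$raw_p, small_shift$raw_p)
  mw <- mann_whitney(a, b + 3.0)
  expect_lt(abs(log10(large_shift$raw_p) - log10(mw$p_value)), 1)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  res <- kruskal_bh(make_expr(3, 12, seed = 2),
                    rep(c("PCM", "MBM", "ECM"), each = 4))
  expect_equal(res$adj_p, bh_bruteforce(res$raw_p), tolerance = 1e-12)
  # the printed worked example
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03), tolerance = 1e-12)
  expect_equal(bh_bruteforce(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  # oracle equivalence over many random p-vectors
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), bh_bruteforce(p),
                 tolerance = 1e-12)
  }
  # monotone in raw p
  p <- runif(30)
  adj <- bh_bruteforce(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
})

test_that("Mann-Whitney: exact small-sample p and rank invariance", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)  # 2/20 labelings, 2-sided
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)
  set.seed(6)
  a <- rnorm(15); b <- rnorm(15) + 1
  p1 <- mann_whitney(a, b)$p_value
  p2 <- mann_whitney(exp(a), exp(b))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), ">= 2")
})

test_that("proportion tests pick the right branch and match enumeration", {
  even <- proportion_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$p_value, 1, tolerance = 1e-9)
  extreme <- matrix(c(10, 0, 0, 10), 2)
  r <- proportion_test(extreme)
  expect_identical(r$method, "fisher")
  expect_equal(r$p_value, fisher_enum(extreme), tolerance = 1e-9)
  # a larger 2x2 with all expected >= 5 and any 2x3 use chi-square
  big <- matrix(c(20, 30, 30, 20), 2)
  expect_identical(proportion_test(big)$method, "chisq")
  wide <- matrix(c(10, 12, 15, 9, 11, 14), 2)
  expect_identical(proportion_test(wide)$method, "chisq")
  expect_error(proportion_test(matrix(c(0, 0, 3, 4), 2)), "zero-margin")
  # more Fisher-vs-enumeration fixtures
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 3) + c(1, 0, 0, 1), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (all(outer(rowSums(tab), colSums(tab)) / sum(tab) >= 5)) next
    expect_equal(proportion_test(tab)$p_value, fisher_enum(tab),
                 tolerance = 1e-9)
  }
})

test_that("correlation matrices match the rank formula and mask correctly", {
  set.seed(9)
  x <- matrix(rnorm(8), ncol = 1, dimnames = list(NULL, "x"))
  y <- matrix(x[, 1]^3 + rnorm(8, sd = 0.2), ncol = 1,
              dimnames = list(NULL, "y"))
  cm <- correlation_matrix(x, y, method = "spearman")
  expect_equal(cm$rho["x", "y"], spearman_d2(x[, 1], y[, 1]),
               tolerance = 1e-9)
  ident <- correlation_matrix(x, x)
  expect_equal(unname(ident$rho[1, 1]), 1, tolerance = 1e-12)
  expect_false(ident$mask[1, 1])
  rev <- correlation_matrix(x, -x)
  expect_equal(unname(rev$rho[1, 1]), -1, tolerance = 1e-12)
  # too few complete pairs
  x2 <- x; x2[1:6, 1] <- NA
  expect_warning(cm2 <- correlation_matrix(x2, y), "4 complete")
  expect_true(is.na(cm2$rho[1, 1]))
})

test_that("DEG log2 fold-changes behave at the identities and the limit", {
  manifest <- data.frame(sample_id = sprintf("S%03d", 1:12),
                         group = rep(c("MBM", "PCM"), each = 6),
                         stringsAsFactors = FALSE)
  expr <- make_expr(10, 12, seed = 14)
  same <- expr
  same[, 7:12] <- same[, 1:6]
  d0 <- deg(same, manifest, "MBM", "PCM")
  expect_equal(d0$log2fc, rep(0, 10), tolerance = 1e-12)
  doubled <- expr
  doubled[, 1:6] <- 2 * doubled[, 7:12] * 1e4  # large TPM kills pseudocount
  doubled[, 7:12] <- doubled[, 7:12] * 1e4
  d1 <- deg(doubled, manifest, "MBM", "PCM")
  expect_equal(d1$log2fc, rep(1, 10), tolerance = 1e-3)
  expect_equal(d1$adj_p, stats::p.adjust(d1$raw_p, "BH"), tolerance = 1e-12)
})

test_that("a planted fold-change is recovered as significant", {
  hits <- vapply(1:25, function(s) {
    cfg <- small_config(seed = 400 + s, n = c(PCM = 30, MBM = 30, ECM = 2),
                        signature_shift = list(MBM = c(mbm_up = 2.0)))
    co <- generate_cohort(cfg)
    d <- deg(co$expression, co$manifest, "MBM", "PCM")
    row <- d[d$gene == "HBB", ]
    row$significant && row$log2fc > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the global null keeps the discovery rate controlled", {
  set.seed(15)
  fracs <- vapply(1:5, function(s) {
    vals <- make_expr(200, 30, seed = 500 + s)
    res <- kruskal_bh(vals, rep(c("PCM", "MBM", "ECM"), each = 10))
    mean(res$adj_p < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(fracs), 0.05 + 2 * se)
})
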