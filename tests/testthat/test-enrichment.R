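# Enrichment statistics: running-sum ES against brute force, permutation
# NES/p calibration, and ssGSEA identities.

test_that("singleton sets at the extremes give ES of +1 / -1", {
  m <- stats::setNames(10:1, sprintf("g%02d", 1:10))
  expect_equal(es(m, "g01", alpha = 0), 1, tolerance = 1e-12)
  expect_equal(es(m, "g10", alpha = 0), -1, tolerance = 1e-12)
})

test_that("ES equals the brute-force running sum on small universes", {
  for (N in c(5, 8, 12)) {
    m <- stats::setNames(seq(N, 1) + 0.5, sprintf("g%02d", seq_len(N)))
    # every singleton position
    for (i in seq_len(N)) {
      g <- sprintf("g%02d", i)
      expect_equal(es(m, g, alpha = 0), es_bruteforce(m, g, alpha = 0),
                   tolerance = 1e-12, info = paste(N, i))
    }
    # random sets, both alpha = 0 and weighted
    set.seed(N)
    for (r in 1:10) {
      g <- sample(names(m), sample(2:(N - 1), 1))
      for (a in c(0, 1)) {
        expect_equal(es(m, g, alpha = a), es_bruteforce(m, g, alpha = a),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("alpha = 0 ES depends on ranks only and stays in [-1, 1]", {
  set.seed(21)
  m <- stats::setNames(rnorm(40), sprintf("g%02d", 1:40))
  g <- sample(names(m), 7)
  e1 <- es(m, g, alpha = 0)
  expect_gte(e1, -1); expect_lte(e1, 1)
  expect_equal(es(exp(m * 3) + 2, g, alpha = 0), e1, tolerance = 1e-12)
})

test_that("ES agrees with an independent GSEA implementation at alpha 1", {
  set.seed(33)
  m <- sort(stats::setNames(rnorm(60), sprintf("g%02d", 1:60)),
            decreasing = TRUE)
  for (r in 1:5) {
    g <- sample(names(m), 8)
    ref <- fgsea::calcGseaStat(unname(m), selectedStats = which(names(m) %in% g),
                               gseaParam = 1)
    expect_equal(es(m, g, alpha = 1), ref, tolerance = 1e-9)
  }
})

test_that("ES contract cases error", {
  m <- stats::setNames(5:1, letters[1:5])
  expect_error(es(m, "zz"), "no gene")
  expect_error(es(m, letters[1:5]), "entire universe")
})

test_that("a set planted at the top is detected with positive NES", {
  set.seed(2)
  m <- stats::setNames(c(sort(runif(10, 5, 9), decreasing = TRUE),
                         rnorm(190)), sprintf("g%03d", 1:200))
  sets <- list(planted = sprintf("g%03d", 1:10),
               random = sprintf("g%03d", 101:120))
  res <- preranked_gsea(m, sets, nperm = 1000, alpha = 1, seed = 7)
  planted <- res[res$set == "planted", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$p, 0.05)
  expect_identical(sign(res$nes), sign(res$es))
  # determinism
  res2 <- preranked_gsea(m, sets, nperm = 1000, alpha = 1, seed = 7)
  expect_identical(res, res2)
  expect_error(preranked_gsea(m, list(), nperm = 1000), "empty")
})

test_that("permutation p-values are calibrated under the null", {
  # shuffled metric carries no signal: p-values should be near-uniform
  fracs <- vapply(1:10, function(s) {
    set.seed(s * 13)
    m <- stats::setNames(rnorm(150), sprintf("g%03d", 1:150))
    sets <- lapply(1:25, function(i) sample(names(m), 10))
    names(sets) <- paste0("S", 1:25)
    res <- preranked_gsea(m, sets, nperm = 200, alpha = 1, seed = s)
    mean(res$p < 0.05)
  }, numeric(1))
  # 250 null sets in total; binomial SE of the mean ~ 0.014
  expect_lt(abs(mean(fracs) - 0.05), 0.045)
  # super-uniformity: Kolmogorov distance from U[0,1] below 0.1
  set.seed(99)
  m <- stats::setNames(rnorm(150), sprintf("g%03d", 1:150))
  sets <- lapply(1:50, function(i) sample(names(m), 10))
  names(sets) <- paste0("S", 1:50)
  res <- preranked_gsea(m, sets, nperm = 1000, alpha = 1, seed = 5)
  ks <- max(abs(stats::ecdf(res$p)(seq(0, 1, 0.01)) - seq(0, 1, 0.01)))
  expect_lt(ks, 0.1 + 1 / length(sets))
})

test_that("ssGSEA matches the brute-force per-position sum", {
  # tiny hand case: N = 4 genes, set = top gene, alpha = 0
  v <- stats::setNames(c(9, 5, 3, 1), c("a", "b", "c", "d"))
  expr <- matrix(v, ncol = 1, dimnames = list(names(v), "s1"))
  got <- ssgsea(expr, list(top = "a"), alpha = 0)
  # hand: P_hit jumps to 1 at position 1; P_miss = 0,1/3,2/3,1
  expect_equal(unname(got[1, 1]), (1 - 0) + (1 - 1/3) + (1 - 2/3) + 0,
               tolerance = 1e-12)
  expect_equal(unname(got[1, 1]), ssgsea_bruteforce(v, "a", alpha = 0),
               tolerance = 1e-12)
  # random fixtures at the default exponent
  expr2 <- make_expr(30, 4, seed = 17)
  sets <- list(A = rownames(expr2)[c(1, 5, 9)],
               B = rownames(expr2)[20:26])
  got2 <- ssgsea(expr2, sets, alpha = 0.25)
  for (j in 1:4) {
    for (k in 1:2) {
      expect_equal(got2[j, k],
                   ssgsea_bruteforce(expr2[, j], sets[[k]], alpha = 0.25),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA is rank-only and deterministic on identical samples", {
  expr <- make_expr(25, 3, seed = 19)
  expr[, 2] <- expr[, 1]
  sets <- list(A = rownames(expr)[1:6])
  sc <- ssgsea(expr, sets)
  expect_identical(sc[1, ], sc[2, ])
  # multiplying a sample (adding a constant on the log scale) changes nothing
  expr2 <- expr
  expr2[, 3] <- expr2[, 3] * 42
  expect_equal(ssgsea(expr2, sets)[3, ], sc[3, ], tolerance = 1e-12)
  # absent sets are NA with a warning; normalization rescales by the range
  expect_warning(sc2 <- ssgsea(expr, c(sets, list(nope = "ZZZ"))), "NA")
  expect_true(is.na(sc2[1, "nope"]))
  norm <- ssgsea_normalize(sc)
  expect_equal(norm, sc / (max(sc) - min(sc)), tolerance = 1e-12)
})
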