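# Cohort z-scores and the composite signature scores / classifiers.

test_that("cohort z-scores use the population SD and normalize exactly", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("A", c("s1", "s2", "s3")))
  z <- cohort_zscores(m)
  # hand computation: mean 2, population SD sqrt(2/3)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(z[1, ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  big <- make_expr(30, 12, seed = 3)
  zb <- cohort_zscores(big)
  expect_lt(max(abs(rowMeans(zb))), 1e-12)
  n <- ncol(zb)
  expect_lt(max(abs(sqrt(rowSums(zb^2) / n) - 1)), 1e-12)

  zs <- cohort_zscores(m, sd_type = "sample")
  expect_equal(unname(zs[1, ]), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("zero-variance genes map to zero z with a warning; 1 sample errors", {
  m <- rbind(A = c(5, 5, 5), B = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(z <- cohort_zscores(m), "zero-variance")
  expect_identical(unname(z["A", ]), c(0, 0, 0))
  expect_error(cohort_zscores(m[, 1, drop = FALSE]), "2 samples")
})

test_that("dysfunction and STING scores equal sums of z-score rows exactly", {
  genes <- c("HAVCR2", "LAG3", "PDCD1", "TMEM173", "CGAS", "CCL5", "CXCL10",
             "IRF3", "OTHER1", "OTHER2")
  expr <- make_expr(10, 8, seed = 7, genes = genes)
  z <- cohort_zscores(expr)
  expect_identical(dysfunction_score(expr),
                   colSums(z[c("HAVCR2", "LAG3", "PDCD1"), ]))
  expect_identical(sting_score(expr),
                   colSums(z[c("TMEM173", "CGAS", "CCL5", "CXCL10", "IRF3"), ]))
})

test_that("samples at the cohort mean / +1 SD score 0 / k on sum-z scores", {
  # per-gene values 4,4,6,6 have cohort mean 5 and population SD exactly 1,
  # so the last two samples sit exactly +1 SD above the mean on every gene
  genes <- c("HAVCR2", "LAG3", "PDCD1")
  expr <- matrix(rep(c(4, 4, 6, 6), each = 3), 3, 4,
                 dimnames = list(genes, paste0("s", 1:4)))
  d <- dysfunction_score(expr)
  expect_equal(unname(d), c(-3, -3, 3, 3), tolerance = 1e-12)
  # per-gene values 4,5,6: the middle sample is at the cohort mean -> 0
  expr2 <- matrix(rep(c(4, 5, 6), each = 3), 3, 3,
                  dimnames = list(genes, paste0("s", 1:3)))
  expect_equal(unname(dysfunction_score(expr2))[2], 0, tolerance = 1e-12)
  # STING analogue: five genes, +1 SD in each -> 5.0
  g5 <- c("TMEM173", "CGAS", "CCL5", "CXCL10", "IRF3")
  expr3 <- matrix(rep(c(4, 4, 6, 6), each = 5), 5, 4,
                  dimnames = list(g5, paste0("s", 1:4)))
  expect_equal(unname(sting_score(expr3)), c(-5, -5, 5, 5), tolerance = 1e-12)
})

test_that("missing genes are reported by name", {
  expr <- make_expr(5, 4, seed = 1, genes = c("HAVCR2", "LAG3", "A", "B", "C"))
  expect_error(dysfunction_score(expr), "PDCD1")
  expect_error(sting_score(expr), "TMEM173")
})

test_that("ifng score is the brute-force mean of log2 z rows", {
  sig <- c("G001", "G002", "G003", "G004", "G005", "G006")
  expr <- make_expr(40, 10, seed = 5)
  sc <- ifng_score(expr, sig)
  z <- cohort_zscores(expr[sig, ], transform = "log2p1")
  expect_equal(sc, colMeans(z), tolerance = 1e-12)
  # singleton signature equals that gene's z row
  expect_equal(ifng_score(expr, "G007"),
               cohort_zscores(expr["G007", , drop = FALSE],
                              transform = "log2p1")["G007", ],
               tolerance = 1e-12)
  expect_error(ifng_score(expr, c("NOPE1", "NOPE2")), "none of the")
})

test_that("z-based scores are invariant to positive rescaling of one gene", {
  expr <- make_expr(20, 9, seed = 8,
                    genes = c("HAVCR2", "LAG3", "PDCD1", "TMEM173", "CGAS",
                              "CCL5", "CXCL10", "IRF3",
                              sprintf("G%03d", 1:12)))
  d1 <- dysfunction_score(expr)
  s1 <- sting_score(expr)
  expr2 <- expr
  expr2["LAG3", ] <- expr2["LAG3", ] * 37.5
  expr2["CCL5", ] <- expr2["CCL5", ] * 0.004
  expect_equal(dysfunction_score(expr2), d1, tolerance = 1e-9)
  expect_equal(sting_score(expr2), s1, tolerance = 1e-9)
})

test_that("tertile TIS classification partitions distinct scores 3/3/3", {
  sig <- sprintf("G%03d", 1:5)
  expr <- make_expr(30, 9, seed = 10)
  res <- tis_classify(expr, sig)
  expect_identical(as.integer(table(res$class)), c(3L, 3L, 3L))
  # class sizes differ by <= 1 for larger distinct cohorts
  expr2 <- make_expr(30, 20, seed = 11)
  res2 <- tis_classify(expr2, sig)
  expect_lte(diff(range(table(res2$class))), 1)
})

test_that("TIS ties and explicit thresholds follow the strict-inequality rule", {
  sig <- sprintf("G%03d", 1:5)
  expr <- make_expr(30, 8, seed = 12)
  # identical scores: replicate one sample everywhere -> all undetermined
  tied <- expr[, rep(1, 6)]
  colnames(tied) <- paste0("s", 1:6)
  suppressWarnings(res <- tis_classify(tied, sig))
  expect_true(all(res$class == "undetermined"))
  # hand-applied rule with explicit extreme thresholds
  sc <- tis_classify(expr, sig)$score
  lo <- min(sc); hi <- max(sc)
  res2 <- tis_classify(expr, sig, thresholds = c(lo + 1e-9, hi - 1e-9))
  expect_identical(as.character(res2$class[which.min(sc)]), "TIS_neg")
  expect_identical(as.character(res2$class[which.max(sc)]), "TIS_pos")
  expect_identical(sum(res2$class == "undetermined"), ncol(expr) - 2L)
  expect_error(tis_classify(expr, sig, thresholds = c(1, 1)),
               "t_low < t_high")
})

test_that("non-functional CD8 rule: strict cutoffs and CD8-zero exclusion", {
  dys <- c(a = 1.5, b = 1.0, c = 2.0, d = 0.5)
  fgf <- c(a = 1, b = 1, c = 10, d = 1)    # cohort median 1 -> a,b not < med
  # median of (1,1,10,1) is 1; a has fgf == median -> strict < fails
  res <- nonfunctional_cd8_classify(dys, fgf, cd8_fraction = c(1, 1, 1, 0))
  expect_false(res$nonfunctional[res$sample_id == "a"])
  fgf2 <- c(a = 0.5, b = 0.5, c = 10, d = 8)  # median 4.25
  res2 <- nonfunctional_cd8_classify(dys, fgf2, cd8_fraction = c(1, 1, 1, 0))
  expect_true(res2$nonfunctional[res2$sample_id == "a"])     # 1.5 > 1, below med
  expect_false(res2$nonfunctional[res2$sample_id == "b"])    # exactly 1.0
  expect_false(res2$eligible[res2$sample_id == "d"])         # cd8 fraction 0
  expect_error(nonfunctional_cd8_classify(numeric(0), numeric(0), numeric(0)),
               "empty")
})
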