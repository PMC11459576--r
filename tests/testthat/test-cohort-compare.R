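test_that("high-mean screen respects the threshold boundary", {
  mat <- rbind(geneIn = c(1.5, 0.6), geneOut = c(1.5, 0.4),
               geneSolo = c(1.2, 1.2))
  colnames(mat) <- c("S1", "S2")
  r <- makeRatios(mat, histology = "SCLC")
  hits <- highMeanScreen(r, "SCLC")
  expect_true("geneIn" %in% hits$gene)     # mean 1.05
  expect_false("geneOut" %in% hits$gene)   # mean 0.95
  expect_equal(hits$gene[1], "geneSolo")   # mean 1.2 leads mean 1.05
  expect_equal(hits$mean_log2, sort(hits$mean_log2, decreasing = TRUE))
  expect_error(highMeanScreen(r, "LUAD"), "unknown histology")
})

test_that("screen membership is invariant to sample order and at-mean additions", {
  set.seed(12)
  mat <- matrix(rnorm(20 * 8, 1, 1), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("S%d", 1:8)))
  r1 <- makeRatios(mat)
  r2 <- makeRatios(mat[, sample(8)])
  expect_equal(sort(highMeanScreen(r1, "SCLC")$gene),
               sort(highMeanScreen(r2, "SCLC")$gene))
  # append one sample sitting exactly at the per-gene mean
  mat3 <- cbind(mat, S9 = rowMeans(mat))
  r3 <- makeRatios(mat3)
  expect_equal(sort(highMeanScreen(r1, "SCLC")$gene),
               sort(highMeanScreen(r3, "SCLC")$gene))
})

test_that("screen recovers truly high genes in noisy cohorts", {
  # 26 genes at true mean 2.0 (SD 0.5) among 204, n = 35 samples
  recovered <- logical(200)
  for (seed in 1:200) {
    set.seed(seed)
    highGenes <- sprintf("hi%02d", 1:26)
    mat <- rbind(
      matrix(rnorm(26 * 35, 2, 0.5), nrow = 26,
             dimnames = list(highGenes, NULL)),
      matrix(rnorm(178 * 35, 0, 0.5), nrow = 178,
             dimnames = list(sprintf("lo%03d", 1:178), NULL))
    )
    colnames(mat) <- sprintf("S%02d", 1:35)
    hits <- highMeanScreen(makeRatios(mat), "SCLC")$gene
    recovered[seed] <- sum(highGenes %in% hits) >= 24
  }
  expect_gte(mean(recovered), 0.9)
})

test_that("prevalence counts use the inclusive cutoff", {
  mat <- rbind(DLL3 = c(rep(1.8, 32), rep(0.2, 3)),
               YAP1 = rep(-1, 35))
  colnames(mat) <- sprintf("S%02d", 1:35)
  r <- makeRatios(mat)
  p <- prevalenceHigh(r, "SCLC", "DLL3")
  expect_equal(p$count, 32)
  expect_equal(p$n, 35)
  expect_equal(formatPercent(p$fraction), 91.4)   # 32/35
  expect_equal(prevalenceHigh(r, "SCLC", "YAP1")$fraction, 0)
  one <- makeRatios(mat[, 1, drop = FALSE])
  expect_true(prevalenceHigh(one, "SCLC", "DLL3")$fraction %in% c(0, 1))
  expect_error(prevalenceHigh(r, "SCLC", "ABSENT"), "absent")
})

test_that("differential testing separates shifted groups and is symmetric", {
  set.seed(14)
  base <- matrix(rnorm(10 * 20, 0, 0.5), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  matA <- base + 3.0
  colnames(matA) <- sprintf("A%02d", 1:20)
  matB <- base
  colnames(matB) <- sprintf("B%02d", 1:20)
  r <- makeRatios(cbind(matA, matB),
                  histology = rep(c("SCLC", "LUAD"), each = 20))
  d <- differentialByGroup(r, "SCLC", "LUAD")
  expect_true(all(d$p < 0.001))
  expect_true(all(d$direction == "higher_in_a"))
  expect_true(all(d$q >= d$p) && all(d$q <= 1))
  # q preserves the ordering of p
  expect_equal(order(d$p), order(d$q))

  dRev <- differentialByGroup(r, "LUAD", "SCLC")
  expect_equal(dRev$p, d$p)
  expect_true(all(dRev$direction == "higher_in_b"))

  # identical groups: p in the no-signal region, direction ns
  same <- cbind(matA, matA)
  colnames(same) <- c(sprintf("A%02d", 1:20), sprintf("B%02d", 1:20))
  rSame <- makeRatios(same, histology = rep(c("SCLC", "LUAD"), each = 20))
  dSame <- differentialByGroup(rSame, "SCLC", "LUAD")
  expect_true(all(dSame$p > 0.9))
  expect_true(all(dSame$direction == "ns"))

  expect_error(differentialByGroup(makeRatios(matA[, 1:2],
                                              histology = "SCLC"),
                                   "SCLC", "SCLC"),
               "at least")
})

test_that("gene-pair correlation matches closed forms and detects rho 0.6", {
  mat <- rbind(LAG3 = seq(-1, 2, length.out = 12))
  mat <- rbind(mat, PDCD1 = mat["LAG3", ], CTLA4 = -mat["LAG3", ])
  colnames(mat) <- sprintf("S%02d", 1:12)
  r <- makeRatios(mat)
  expect_equal(genePairCorrelation(r, "SCLC", "LAG3", "PDCD1")$r, 1)
  expect_equal(genePairCorrelation(r, "SCLC", "LAG3", "CTLA4")$r, -1)

  # power at true rank correlation 0.6, n = 35
  rho <- 2 * sin(pi * 0.6 / 6)  # Pearson rho giving Spearman 0.6
  rejections <- 0L
  for (seed in 1:500) {
    set.seed(seed)
    x <- rnorm(35)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(35)
    m <- rbind(gA = x, gB = y)
    colnames(m) <- sprintf("S%02d", 1:35)
    out <- genePairCorrelation(makeRatios(m), "SCLC", "gA", "gB")
    if (out$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 500, 0.8)
})
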