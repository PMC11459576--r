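test_that("IHC binarization is strictly greater-than the cutoff", {
  expect_false(binarizeIhc(10))   # boundary: 10 is negative
  expect_true(binarizeIhc(11))
  expect_true(binarizeIhc(300))
  expect_false(binarizeIhc(0))
  expect_error(binarizeIhc(301), "0, 300")
  expect_error(binarizeIhc(-1), "0, 300")
})

test_that("agreement tables cross-tabulate and align on sample ids", {
  t1 <- agreementTable(c(TRUE, TRUE, FALSE, FALSE),
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(t1[, c("tp", "fp", "fn", "tn")],
               data.frame(tp = 2, fp = 0, fn = 0, tn = 2))
  t2 <- agreementTable(rep(TRUE, 3), rep(FALSE, 3))
  expect_equal(t2$fp, 3)

  test <- c(A = TRUE, B = FALSE, C = TRUE)
  ref <- c(B = FALSE, C = FALSE, D = TRUE)
  t3 <- agreementTable(test, ref)
  expect_equal(t3$n_excluded, 2)  # A and D dropped
  expect_equal(t3$tp + t3$fp + t3$fn + t3$tn, 2)
  expect_error(agreementTable(c(A = TRUE), c(B = TRUE)), "overlapping")
})

test_that("per-marker metrics reproduce the reconstructed 2x2 tables", {
  tabs <- reconstructedTables()
  ascl1 <- agreementMetrics(tabs[tabs$marker == "ASCL1", ])
  expect_equal(metricValue(ascl1, "PPA"), 100)
  expect_equal(round(metricValue(ascl1, "NPA"), 1), 66.7)

  neurod1 <- agreementMetrics(tabs[tabs$marker == "NEUROD1", ])
  expect_equal(metricValue(neurod1, "PPA"), 100)
  expect_equal(round(metricValue(neurod1, "NPA"), 1), 87.5)

  pou2f3 <- agreementMetrics(tabs[tabs$marker == "POU2F3", ])
  expect_equal(metricValue(pou2f3, "PPA"), 50)
  expect_equal(metricValue(pou2f3, "NPA"), 100)

  # YAP1 has no positives by either assay: PPA and PPV not assessable
  yap1 <- agreementMetrics(tabs[tabs$marker == "YAP1", ])
  expect_true(is.na(metricValue(yap1, "PPA")))
  expect_true(is.na(metricValue(yap1, "PPV")))
  expect_equal(metricValue(yap1, "NPA"), 100)
})

test_that("pooling sums cells before computing metrics", {
  pooled <- agreementMetrics(reconstructedTables())
  expect_equal(round(metricValue(pooled, "PPA"), 1), 93.3)  # 14/15
  expect_equal(round(metricValue(pooled, "NPA"), 1), 93.9)  # 31/33
  expect_equal(round(metricValue(pooled, "OPA"), 1), 93.8)  # 45/48
})

test_that("the reconstructed tables are the unique joint solution", {
  # exhaustive enumeration over all 2x2 tables with n = 12 per marker,
  # constrained by the printed per-marker and pooled percentages at
  # 1-decimal rounding
  r1 <- function(x) floor(x * 10 + 0.5) / 10
  grid <- expand.grid(tp = 0:12, fp = 0:12, fn = 0:12)
  grid$tn <- 12 - grid$tp - grid$fp - grid$fn
  grid <- grid[grid$tn >= 0, ]
  ppa <- ifelse(grid$tp + grid$fn == 0, NA,
                100 * grid$tp / (grid$tp + grid$fn))
  npa <- ifelse(grid$tn + grid$fp == 0, NA,
                100 * grid$tn / (grid$tn + grid$fp))
  candA <- grid[!is.na(ppa) & ppa == 100 & !is.na(npa) & r1(npa) == 66.7, ]
  candN <- grid[!is.na(ppa) & ppa == 100 & !is.na(npa) & r1(npa) == 87.5, ]
  candP <- grid[!is.na(ppa) & r1(ppa) == 50 & !is.na(npa) & npa == 100, ]
  candY <- grid[grid$tp + grid$fn == 0 & grid$tp + grid$fp == 0 &
                  !is.na(npa) & npa == 100, ]
  solutions <- 0L
  found <- NULL
  for (a in seq_len(nrow(candA))) for (n in seq_len(nrow(candN)))
    for (p in seq_len(nrow(candP))) for (y in seq_len(nrow(candY))) {
      joint <- rbind(candA[a, ], candN[n, ], candP[p, ], candY[y, ])
      TP <- sum(joint$tp); FP <- sum(joint$fp)
      FN <- sum(joint$fn); TN <- sum(joint$tn)
      if (r1(100 * TP / (TP + FN)) == 93.3 &&
          r1(100 * TN / (TN + FP)) == 93.9 &&
          r1(100 * (TP + TN) / 48) == 93.8) {
        solutions <- solutions + 1L
        found <- joint
      }
    }
  expect_equal(solutions, 1L)
  ref <- reconstructedTables()
  expect_equal(unname(as.matrix(found[, c("tp", "fp", "fn", "tn")])),
               unname(as.matrix(ref[, c("tp", "fp", "fn", "tn")])))
})

test_that("swapping test and reference swaps PPA/PPV and NPA/NPV", {
  set.seed(7)
  for (i in 1:1000) {
    cells <- as.integer(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    tab <- data.frame(tp = cells[1], fp = cells[2],
                      fn = cells[3], tn = cells[4])
    swapped <- data.frame(tp = tab$tp, fp = tab$fn,
                          fn = tab$fp, tn = tab$tn)
    m1 <- agreementMetrics(tab)
    m2 <- agreementMetrics(swapped)
    expect_equal(metricValue(m1, "PPA"), metricValue(m2, "PPV"))
    expect_equal(metricValue(m1, "NPA"), metricValue(m2, "NPV"))
    expect_equal(metricValue(m1, "OPA"), metricValue(m2, "OPA"))
  }
})

test_that("pooled OPA equals the cellwise identity on random table sets", {
  set.seed(8)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    tabs <- data.frame(tp = sample(0:20, k, TRUE), fp = sample(0:20, k, TRUE),
                       fn = sample(0:20, k, TRUE), tn = sample(0:20, k, TRUE))
    n <- sum(tabs)
    if (n == 0) next
    pooled <- agreementMetrics(tabs)
    expect_equal(metricValue(pooled, "OPA"),
                 100 * (sum(tabs$tp) + sum(tabs$tn)) / n)
  }
})

test_that("Wilson intervals contain the point estimate within [0, 100]", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    x <- sample(0:n, 1)
    ci <- wilsonInterval(x, n)
    expect_gte(ci[["hi"]] + 1e-9, x / n)
    expect_lte(ci[["lo"]] - 1e-9, x / n)
    expect_gte(ci[["lo"]], 0)
    expect_lte(ci[["hi"]], 1)
  }
})

test_that("paired correlation handles closed forms and degenerate input", {
  x <- 1:10
  expect_equal(correlatePaired(x, 2 * x + 1, method = "pearson")$r, 1)
  expect_equal(correlatePaired(x, rev(x), method = "spearman")$r, -1)
  expect_error(correlatePaired(x, rep(1, 10)), "degenerate")
  expect_error(correlatePaired(1:2, 1:2), "three finite pairs")
  # log2 transform route used for linear counts vs TPM
  out <- correlatePaired(2^x, 2^(x + 0.1), method = "pearson",
                         transform = "log2")
  expect_gt(out$r, 0.99)
  expect_equal(out$n, 10)
})

test_that("panel-vs-TPM pairs at realistic noise correlate above 0.9", {
  # 17 paired samples, true log-scale slope 1, noise SD 0.3
  hits <- 0L
  for (seed in 1:500) {
    set.seed(seed)
    truth <- rnorm(17, 0, 1.5)
    obs <- truth + rnorm(17, 0, 0.3)
    if (correlatePaired(truth, obs, method = "pearson")$r > 0.9)
      hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.9)
})
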