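test_that("background threshold is mean + k*SD of negative controls", {
  expect_equal(backgroundThreshold(c(5, 5, 5, 5)), 5.0)
  expect_equal(backgroundThreshold(c(2, 4, 6, 8)),
               5 + 2 * sd(c(2, 4, 6, 8)))  # ~10.164
  expect_equal(backgroundThreshold(c(0, 0)), 0.0)
  expect_equal(backgroundThreshold(c(2, 4, 6, 8), kSd = 3),
               5 + 3 * sd(c(2, 4, 6, 8)))
  expect_error(backgroundThreshold(5), "at least two")
})

test_that("positive factors are geometric-mean ratios with unit gm", {
  two <- matrix(c(100, 100, 400, 400), nrow = 2,
                dimnames = list(c("P1", "P2"), c("A", "B")))
  p <- positiveFactors(two)
  expect_equal(unname(p), c(2.0, 0.5))

  same <- matrix(c(50, 80, 50, 80), nrow = 2,
                 dimnames = list(c("P1", "P2"), c("A", "B")))
  expect_equal(unname(positiveFactors(same)), c(1, 1))

  # scaling one sample by c divides its factor by c (up to the cohort gm)
  set.seed(4)
  m <- matrix(rexp(12, 1 / 200) + 1, nrow = 3,
              dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
  p1 <- positiveFactors(m)
  m2 <- m; m2[, "S2"] <- m2[, "S2"] * 8
  p2 <- positiveFactors(m2)
  expect_equal(p2[["S2"]] / p1[["S2"]] * 8^(3 / 4), 1, tolerance = 1e-12)
  expect_equal(prod(p2)^(1 / length(p2)), 1, tolerance = 1e-9)

  m2["P1", "S3"] <- 0
  expect_error(positiveFactors(m2), "S3")
})

test_that("housekeeping factors follow the hand-computed example", {
  # per-sample geometric means 100 and 225; cohort gm 150
  hk <- matrix(c(100, 100, 225, 225), nrow = 2,
               dimnames = list(c("H1", "H2"), c("A", "B")))
  h <- housekeepingFactors(hk)
  expect_equal(unname(h), c(1.5, 2 / 3))

  doubled <- hk; doubled[, "A"] <- hk[, "A"] * 2
  h2 <- housekeepingFactors(doubled)
  expect_equal(h2[["A"]] / h[["A"]] * 2^(1 / 2), 1, tolerance = 1e-12)
})

test_that("normalization of trivial cohorts leaves floored counts intact", {
  # identical samples: p = h = 1 everywhere, normalized = floored raw
  pcs <- toyCounts(ids = c("S1", "S2", "REF"))
  norm <- normalizeCounts(pcs)
  model <- normalizationModel(norm)
  expect_equal(unname(model@posFactor), rep(1, 3))
  expect_equal(unname(model@hkFactor), rep(1, 3))
  b <- model@background
  floored <- pmax(panelCounts(pcs),
                  matrix(b, nrow(pcs), ncol(pcs), byrow = TRUE))
  expect_equal(normalizedCounts(norm), floored)
})

test_that("log2 ratios against the in-batch reference match closed forms", {
  pcs <- toyCounts(edits = list(
    list(gene = "ASCL1", sample = "S1", count = 400),
    list(gene = "NEUROD1", sample = "S1", count = 300)
  ))
  r <- ratiosToReference(normalizeCounts(pcs))
  mat <- log2Ratios(r)
  expect_equal(mat["ASCL1", "S1"], 2.0)
  expect_equal(mat["NEUROD1", "S1"], log2(3), tolerance = 1e-12)
  # a reference against itself is exactly zero
  expect_true(all(mat[, "REF"] == 0))
  # untouched genes in identical lanes sit at ratio zero
  expect_equal(mat["YAP1", "S2"], 0)
})

test_that("log2 ratios are invariant to joint rescaling of sample and reference", {
  pcs <- toyCounts(edits = list(
    list(gene = "ASCL1", sample = "S1", count = 400)))
  norm <- normalizeCounts(pcs)
  r1 <- log2Ratios(ratiosToReference(norm))
  # rescale every normalized count (all samples share the batch reference)
  scaled <- norm
  SummarizedExperiment::assay(scaled, "normalized") <-
    normalizedCounts(norm) * 7
  r2 <- log2Ratios(ratiosToReference(scaled))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("raising a raw endogenous count never decreases its ratio", {
  set.seed(21)
  for (rep in 1:20) {
    count0 <- sample(50:500, 1)
    pcs0 <- toyCounts(edits = list(
      list(gene = "DLL3", sample = "S1", count = count0)))
    pcs1 <- toyCounts(edits = list(
      list(gene = "DLL3", sample = "S1", count = count0 + sample(1:200, 1))))
    r0 <- log2Ratios(ratiosToReference(normalizeCounts(pcs0)))["DLL3", "S1"]
    r1 <- log2Ratios(ratiosToReference(normalizeCounts(pcs1)))["DLL3", "S1"]
    expect_gte(r1, r0)
  }
})

test_that("normalization factors conserve the geometric mean", {
  for (seed in 1:5) {
    sim <- simulateCohort(simConfig(n_samples = 8, n_batches = 2,
                                    seed = seed))
    model <- normalizationModel(normalizeCounts(sim$counts))
    expect_equal(mean(log(model@posFactor)), 0, tolerance = 1e-9)
    expect_equal(mean(log(model@hkFactor)), 0, tolerance = 1e-9)
  }
})

test_that("a missing batch reference is rejected when computing ratios", {
  pcs <- toyCounts()
  norm <- normalizeCounts(pcs)
  # forge a colData without any reference flag
  SummarizedExperiment::colData(norm)$IsReference <- FALSE
  expect_error(ratiosToReference(norm), "reference")
})

test_that("zero-background lanes fall back to the pseudo-count offset", {
  # all negatives zero -> threshold 0 -> a zero endogenous count survives
  pcs <- toyCounts(edits = c(
    lapply(c("NEG_A", "NEG_B", "NEG_C"), function(g)
      list(gene = g, sample = "S1", count = 0)),
    lapply(c("NEG_A", "NEG_B", "NEG_C"), function(g)
      list(gene = g, sample = "S2", count = 0)),
    lapply(c("NEG_A", "NEG_B", "NEG_C"), function(g)
      list(gene = g, sample = "REF", count = 0)),
    list(list(gene = "GENE001", sample = "S1", count = 0))
  ))
  r <- ratiosToReference(normalizeCounts(pcs), pseudoCount = 0.5)
  expect_true(all(is.finite(log2Ratios(r))))
  expect_equal(log2Ratios(r)["GENE001", "S1"], log2(0.5 / 100.5),
               tolerance = 1e-12)
})
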