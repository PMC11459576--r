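#' Negative-control background threshold
#'
#' The background threshold of one lane is the mean plus `kSd` sample
#' standard deviations (n-1 denominator) of its negative-control probe
#' counts. Counts are later floored at this threshold so that log2 is
#' always defined for thresholded lanes.
#'
#' @param negatives numeric vector of negative-control counts for one sample
#'   (at least two probes).
#' @param kSd number of standard deviations above the mean (default 2).
#' @return scalar threshold, in counts.
#' @examples
#' backgroundThreshold(c(2, 4, 6, 8))  # 5 + 2*sd = 10.164
#' @export
backgroundThreshold <- function(negatives, kSd = 2) {
  if (length(negatives) < 2)
    stop("at least two negative-control probes are required")
  if (any(negatives < 0)) stop("negative-control counts must be >= 0")
  mean(negatives) + kSd * sd(negatives)
}

#' Positive-control scaling factors
#'
#' Per-sample factor p_s = (cohort geometric mean of the per-sample
#' geometric means of positive-control counts) / (geometric mean of sample
#' s). The returned factors have geometric mean exactly 1, so scaling
#' conserves overall signal.
#'
#' @param positives numeric matrix of positive-control counts
#'   (probes x samples), all strictly positive.
#' @return named numeric vector of factors, one per sample.
#' @export
positiveFactors <- function(positives) {
  positives <- as.matrix(positives)
  zero <- colnames(positives)[apply(positives <= 0, 2, any)]
  if (length(zero))
    stop("zero positive-control count in sample(s): ",
         paste(zero, collapse = ", "))
  gms <- apply(positives, 2, geomMean)
  geomMean(gms) / gms
}

#' Housekeeping content factors
#'
#' Same geometric-mean construction as [positiveFactors()], applied to the
#' selected housekeeping genes after positive-control scaling.
#'
#' @param housekeepers numeric matrix (selected housekeeping genes x
#'   samples), strictly positive.
#' @return named numeric vector of factors with geometric mean 1.
#' @export
housekeepingFactors <- function(housekeepers) {
  housekeepers <- as.matrix(housekeepers)
  if (nrow(housekeepers) < 1) stop("no housekeeping genes supplied")
  zero <- colnames(housekeepers)[apply(housekeepers <= 0, 2, any)]
  if (length(zero))
    stop("zero housekeeping count in sample(s): ", paste(zero, collapse = ", "))
  gms <- apply(housekeepers, 2, geomMean)
  geomMean(gms) / gms
}

#' geNorm stability measure M
#'
#' For each candidate reference gene j, M_j is the mean over all other
#' candidates k of the across-sample standard deviation (n-1 denominator)
#' of the pairwise log2 expression ratio log2(a_j) - log2(a_k). Low M
#' means stable relative expression. Computed through the covariance
#' identity Var(x_j - x_k) = Var(x_j) + Var(x_k) - 2 Cov(x_j, x_k).
#'
#' @param logExpr numeric matrix of log2 expression, candidate genes x
#'   samples (>= 3 genes, >= 3 samples).
#' @return named numeric vector of M values.
#' @export
geNormMValues <- function(logExpr) {
  logExpr <- as.matrix(logExpr)
  if (nrow(logExpr) < 3)
    stop("geNorm requires at least three candidate genes")
  if (ncol(logExpr) < 3)
    stop("geNorm requires at least three samples")
  if (any(!is.finite(logExpr))) stop("log expression must be finite")
  cv <- stats::cov(t(logExpr))
  v <- diag(cv)
  pairSd <- sqrt(pmax(outer(v, v, "+") - 2 * cv, 0))
  m <- rowSums(pairSd) / (nrow(logExpr) - 1)
  setNames(m, rownames(logExpr))
}

#' geNorm reference-gene selection
#'
#' Iteratively eliminates the candidate with the highest stability measure
#' M (recomputed each round) down to the final two genes, then walks the
#' pairwise-variation series V(n/n+1) = SD across samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the per-sample geometric mean of
#' the n most stable genes. The selected set is the smallest
#' n >= `minHousekeepers` with V(n/n+1) < `vThreshold`; when no n
#' qualifies, all candidates are kept with a warning.
#'
#' @param logExpr numeric matrix of log2 expression, candidates x samples.
#' @param vThreshold pairwise-variation cutoff (default 0.15, the
#'   conventional geNorm value).
#' @param minHousekeepers minimum number of reference genes to retain
#'   (default 3).
#' @return a [GeNormResult-class].
#' @export
geNormSelect <- function(logExpr, vThreshold = 0.15, minHousekeepers = 3) {
  logExpr <- as.matrix(logExpr)
  nGenes <- nrow(logExpr)
  if (nGenes < 3) stop("geNorm requires at least three candidate genes")
  if (minHousekeepers < 2) stop("minHousekeepers must be >= 2")
  if (minHousekeepers > nGenes)
    stop("minHousekeepers exceeds the number of candidates")

  finalM <- geNormMValues(logExpr)
  elimination <- character()
  remaining <- rownames(logExpr)
  while (length(remaining) > 2) {
    m <- geNormMValues(logExpr[remaining, , drop = FALSE])
    worst <- names(m)[which.max(m)]
    elimination <- c(elimination, worst)
    remaining <- setdiff(remaining, worst)
  }
  # stability ranking, most stable first; the final pair is ordered by its
  # last-round M (ties keep matrix order)
  lastM <- geNormMValues(logExpr[c(remaining, elimination[length(elimination)]),
                                 , drop = FALSE])[remaining]
  ranking <- c(remaining[order(lastM)], rev(elimination))

  vSeries <- numeric()
  if (nGenes > 2) {
    nfLog <- vapply(seq_len(nGenes), function(n)
      colMeans(logExpr[ranking[seq_len(n)], , drop = FALSE]),
      numeric(ncol(logExpr)))
    for (n in 2:(nGenes - 1))
      vSeries[paste0(n, "/", n + 1)] <- sd(nfLog[, n] - nfLog[, n + 1])
  }

  selected <- ranking
  thresholdMet <- TRUE
  if (nGenes > minHousekeepers) {
    candidates <- minHousekeepers:(nGenes - 1)
    ok <- candidates[vSeries[paste0(candidates, "/", candidates + 1)] <
                       vThreshold]
    if (length(ok)) {
      selected <- ranking[seq_len(ok[1])]
    } else {
      thresholdMet <- FALSE
      warning("no n satisfied V(n/n+1) < ", vThreshold,
              "; keeping all ", nGenes, " candidates")
    }
  }
  new("GeNormResult",
      mValues = finalM,
      eliminationOrder = elimination[!elimination %in% selected],
      vSeries = vSeries,
      selected = selected,
      thresholdMet = thresholdMet)
}

#' Normalize a panel cohort
#'
#' Applies the normalization chain in fixed order: (1) floor each sample's
#' counts at its negative-control background threshold, (2) scale by the
#' positive-control factor p_s, (3) select housekeeping genes with geNorm
#' and scale by the content factor h_s. The normalized count is therefore
#' `max(raw, b_s) * p_s * h_s`.
#'
#' @param x a [PanelCountSet-class].
#' @param kSd background threshold stringency (default 2 SD).
#' @param vThreshold,minHousekeepers passed to [geNormSelect()].
#' @return `x` with an added `normalized` assay and the
#'   [NormalizationModel-class] in `metadata(x)$normalization`.
#' @examples
#' sim <- simulateCohort(simConfig(n_samples = 6, seed = 7))
#' norm <- normalizeCounts(sim$counts)
#' normalizationModel(norm)
#' @export
normalizeCounts <- function(x, kSd = 2, vThreshold = 0.15,
                            minHousekeepers = 3) {
  stopifnot(is(x, "PanelCountSet"))
  cts <- assay(x, "counts")
  cc <- codeClass(x)

  b <- apply(cts[cc == "Negative", , drop = FALSE], 2,
             backgroundThreshold, kSd = kSd)
  floored <- pmax(cts, matrix(b, nrow(cts), ncol(cts), byrow = TRUE))

  p <- positiveFactors(floored[cc == "Positive", , drop = FALSE])
  scaled <- sweep(floored, 2, p, "*")

  hkGenes <- rownames(x)[cc == "Housekeeping"]
  genorm <- geNormSelect(log2(scaled[hkGenes, , drop = FALSE]),
                         vThreshold = vThreshold,
                         minHousekeepers = min(minHousekeepers,
                                               length(hkGenes)))
  h <- housekeepingFactors(
    scaled[selectedHousekeepers(genorm), , drop = FALSE])
  normalized <- sweep(scaled, 2, h, "*")

  model <- new("NormalizationModel", background = b, posFactor = p,
               hkFactor = h, genorm = genorm)
  assay(x, "normalized") <- normalized
  metadata(x)$normalization <- model
  x
}

#' Log2 ratios versus the in-batch universal reference
#'
#' For every endogenous gene and sample, subtracts the normalized log2
#' count of the universal-reference sample of the same batch from the
#' sample's normalized log2 count. Reference samples are retained with
#' all-zero ratios. When any normalized endogenous count is zero (possible
#' only if a lane's background threshold is zero), `pseudoCount` is added
#' to every endogenous cell before taking log2 so ratios stay finite.
#'
#' @param x a normalized [PanelCountSet-class] (see [normalizeCounts()]).
#' @param pseudoCount offset used only when zeros are present (default 0.5).
#' @return a [PanelRatios-class] over the endogenous genes.
#' @export
ratiosToReference <- function(x, pseudoCount = 0.5) {
  stopifnot(is(x, "PanelCountSet"))
  norm <- normalizedCounts(x)
  cd <- colData(x)
  endo <- rownames(x)[codeClass(x) == "Endogenous"]
  mat <- norm[endo, , drop = FALSE]
  if (any(mat <= 0)) mat <- mat + pseudoCount

  batches <- as.character(cd$BatchID)
  refIdx <- which(cd$IsReference)
  refMap <- setNames(colnames(x)[refIdx], batches[refIdx])
  missing <- setdiff(unique(batches), names(refMap))
  if (length(missing))
    stop("batch(es) without a reference sample: ",
         paste(missing, collapse = ", "))

  lg <- log2(mat)
  ratios <- lg - lg[, refMap[batches], drop = FALSE]
  dimnames(ratios) <- dimnames(mat)
  ratios[, refIdx] <- 0  # exact zeros for a reference against itself

  se <- SummarizedExperiment(assays = list(log2ratio = ratios),
                             colData = cd[colnames(mat), , drop = FALSE])
  out <- new("PanelRatios", se)
  metadata(out)$referenceMap <- refMap
  out
}
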