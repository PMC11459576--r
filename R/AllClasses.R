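#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

validCodeClasses <- c("Endogenous", "Housekeeping", "Positive", "Negative")

#' PanelCountSet: raw counts from a targeted hybridization-counting panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding raw probe counts
#' (genes x samples) from a NanoString-style targeted expression panel.
#' `rowData` carries the panel definition (`CodeClass` one of Endogenous,
#' Housekeeping, Positive, Negative; `NominalConc` in fM for Positive
#' probes); `colData` carries the sample sheet (`BatchID`, `PatientID`,
#' `TissueSite`, `Histology`, `IsReference`, `TumorPct`). Every batch must
#' contain exactly one universal-reference sample (`IsReference == TRUE`),
#' the denominator of all log2 ratios.
#'
#' @export
setClass("PanelCountSet", contains = "SummarizedExperiment")

setValidity("PanelCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts contain missing cells")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cts != floor(cts))) msg <- c(msg, "counts must be integers")
    }
  }
  rd <- rowData(object)
  if (!"CodeClass" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'CodeClass'")
  else {
    cc <- as.character(rd$CodeClass)
    bad <- setdiff(unique(cc), validCodeClasses)
    if (length(bad))
      msg <- c(msg, paste0("unknown code class: ", paste(bad, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "gene identifiers must be unique")
    for (cl in c("Housekeeping", "Positive", "Negative"))
      if (!any(cc == cl))
        msg <- c(msg, paste0("panel needs at least one ", cl, " probe"))
    if (any(cc == "Positive")) {
      conc <- rd$NominalConc[cc == "Positive"]
      if (anyNA(conc) || any(conc <= 0))
        msg <- c(msg, "Positive probes need strictly positive NominalConc")
      else if (anyDuplicated(conc))
        msg <- c(msg, "Positive NominalConc values must be pairwise distinct")
    }
  }
  cd <- colData(object)
  for (col in c("BatchID", "IsReference"))
    if (!col %in% colnames(cd))
      msg <- c(msg, paste0("colData must contain '", col, "'"))
  if (all(c("BatchID", "IsReference") %in% colnames(cd))) {
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "sample identifiers must be unique")
    nref <- tapply(cd$IsReference, as.character(cd$BatchID), sum)
    off <- names(nref)[nref != 1L]
    if (length(off))
      msg <- c(msg, paste0("each batch needs exactly one reference sample; ",
                           "offending batch(es): ", paste(off, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' GeNormResult: reference-gene stability selection trace
#'
#' Records the geNorm run over candidate housekeeping genes: the stability
#' measure M per gene (mean, over partner genes, of the across-sample SD of
#' the pairwise log2 expression ratio), the iterative elimination order
#' (least stable first), the pairwise-variation series V(n/n+1), and the
#' selected reference-gene set.
#'
#' @slot mValues named numeric, final-round M per candidate gene.
#' @slot eliminationOrder character, genes removed in order (least stable
#'   first); the two most stable genes are never eliminated.
#' @slot vSeries named numeric, V(n/n+1) keyed "n/n+1".
#' @slot selected character, the selected housekeeping genes.
#' @slot thresholdMet logical, FALSE when no n satisfied the V threshold and
#'   all candidates were kept.
#' @export
setClass("GeNormResult", representation(
  mValues = "numeric",
  eliminationOrder = "character",
  vSeries = "numeric",
  selected = "character",
  thresholdMet = "logical"
))

setValidity("GeNormResult", function(object) {
  msg <- character()
  if (any(object@mValues < 0)) msg <- c(msg, "M values must be >= 0")
  if (length(object@vSeries) && any(object@vSeries < 0))
    msg <- c(msg, "V values must be >= 0")
  if (length(intersect(object@selected, object@eliminationOrder)))
    msg <- c(msg, "selected genes cannot appear in the elimination order")
  if (length(msg)) msg else TRUE
})

#' NormalizationModel: per-sample normalization factors
#'
#' Captures the full normalization chain for one cohort: the per-sample
#' negative-control background threshold b_s (counts are floored at b_s),
#' the positive-control scaling factor p_s, the housekeeping content factor
#' h_s (both constrained to geometric mean 1 across samples), and the
#' geNorm selection trace. The composite per-sample factor is p_s * h_s.
#'
#' @slot background named numeric, per-sample background threshold (counts).
#' @slot posFactor named numeric, per-sample positive-control factor.
#' @slot hkFactor named numeric, per-sample housekeeping factor.
#' @slot genorm a [GeNormResult-class].
#' @export
setClass("NormalizationModel", representation(
  background = "numeric",
  posFactor = "numeric",
  hkFactor = "numeric",
  genorm = "GeNormResult"
))

setValidity("NormalizationModel", function(object) {
  msg <- character()
  if (any(object@background < 0)) msg <- c(msg, "background must be >= 0")
  if (any(object@posFactor <= 0)) msg <- c(msg, "positive factors must be > 0")
  if (any(object@hkFactor <= 0))
    msg <- c(msg, "housekeeping factors must be > 0")
  if (length(object@posFactor) > 0 &&
      abs(log(geomMean(object@posFactor))) > 1e-9)
    msg <- c(msg, "positive factors must have geometric mean 1")
  if (length(object@hkFactor) > 0 &&
      abs(log(geomMean(object@hkFactor))) > 1e-9)
    msg <- c(msg, "housekeeping factors must have geometric mean 1")
  if (length(msg)) msg else TRUE
})

#' PanelRatios: normalized log2 ratios against the universal reference
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `log2ratio` holds, for every endogenous gene and sample, the normalized
#' log2 count minus the normalized log2 count of the universal-reference
#' sample run in the same batch. Reference samples are retained with
#' all-zero ratios but are excluded from cohort summaries downstream.
#' `metadata(x)$referenceMap` maps batch to reference sample id.
#'
#' @export
setClass("PanelRatios", contains = "SummarizedExperiment")

setValidity("PanelRatios", function(object) {
  msg <- character()
  if (!"log2ratio" %in% assayNames(object))
    msg <- c(msg, "assay 'log2ratio' is required")
  else if (any(!is.finite(assay(object, "log2ratio"))))
    msg <- c(msg, "log2 ratios must be finite")
  if (!"IsReference" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'IsReference'")
  else {
    ref <- colnames(object)[colData(object)$IsReference]
    if (length(ref) && "log2ratio" %in% assayNames(object) &&
        any(assay(object, "log2ratio")[, ref, drop = FALSE] != 0))
      msg <- c(msg, "reference samples must have all-zero ratios")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PanelCountSet", function(object) {
  cc <- as.character(rowData(object)$CodeClass)
  cat("PanelCountSet:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  probes:", sum(cc == "Endogenous"), "endogenous,",
      sum(cc == "Housekeeping"), "housekeeping,",
      sum(cc == "Positive"), "positive,",
      sum(cc == "Negative"), "negative\n")
  cat("  batches:", length(unique(colData(object)$BatchID)),
      "| reference samples:", sum(colData(object)$IsReference), "\n")
})

setMethod("show", "GeNormResult", function(object) {
  cat("GeNormResult:", length(object@mValues), "candidates;",
      length(object@selected), "selected",
      if (!object@thresholdMet) "(V threshold not met; all kept)" else "",
      "\n  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "NormalizationModel", function(object) {
  cat("NormalizationModel over", length(object@posFactor), "samples\n")
  cat("  background threshold: median",
      format(median(object@background), digits = 4), "counts\n")
  cat("  housekeepers:", paste(object@genorm@selected, collapse = ", "), "\n")
})

setMethod("show", "PanelRatios", function(object) {
  cat("PanelRatios:", nrow(object), "genes x", ncol(object), "samples",
      "(", sum(colData(object)$IsReference), "reference )\n")
})
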