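#' Construct a PanelCountSet from counts, panel definition and sample sheet
#'
#' @param counts integer matrix, genes x samples; dimnames required.
#' @param panel data.frame with columns `gene`, `code_class` and (for
#'   Positive probes) `nominal_conc` in fM.
#' @param samples data.frame with columns `sample_id`, `batch_id`,
#'   `is_reference` and optionally `patient_id`, `tissue_site`, `histology`,
#'   `tumor_pct`.
#' @return a validated [PanelCountSet-class].
#' @examples
#' sim <- simulateCohort(simConfig(n_samples = 4, seed = 1))
#' pcs <- sim$counts
#' pcs
#' @export
PanelCountSet <- function(counts, panel, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  missing <- setdiff(rownames(counts), panel$gene)
  if (length(missing))
    stop("gene(s) absent from panel definition: ",
         paste(head(missing, 5), collapse = ", "))
  missingS <- setdiff(colnames(counts), samples$sample_id)
  if (length(missingS))
    stop("sample(s) absent from sample sheet: ",
         paste(head(missingS, 5), collapse = ", "))
  badNeg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(badNeg))
    stop("negative count for gene ", rownames(counts)[badNeg[1, 1]],
         ", sample ", colnames(counts)[badNeg[1, 2]])
  badFrac <- which(counts != floor(counts), arr.ind = TRUE)
  if (nrow(badFrac))
    stop("fractional count for gene ", rownames(counts)[badFrac[1, 1]],
         ", sample ", colnames(counts)[badFrac[1, 2]])
  p <- panel[match(rownames(counts), panel$gene), , drop = FALSE]
  s <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rd <- DataFrame(
    CodeClass = as.character(p$code_class),
    NominalConc = if ("nominal_conc" %in% names(p))
      as.numeric(p$nominal_conc) else NA_real_,
    row.names = rownames(counts)
  )
  opt <- function(col, default) {
    if (col %in% names(s)) s[[col]] else rep(default, nrow(s))
  }
  cd <- DataFrame(
    BatchID = as.character(s$batch_id),
    PatientID = as.character(opt("patient_id", NA_character_)),
    TissueSite = as.character(opt("tissue_site", NA_character_)),
    Histology = as.character(opt("histology", NA_character_)),
    IsReference = as.logical(s$is_reference),
    TumorPct = as.numeric(opt("tumor_pct", NA_real_)),
    row.names = colnames(counts)
  )
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("PanelCountSet", se)
}

#' @describeIn PanelCountSet probe code classes (named character vector).
#' @param x a `PanelCountSet`.
#' @export
codeClass <- function(x) {
  setNames(as.character(rowData(x)$CodeClass), rownames(x))
}

#' Raw counts of a PanelCountSet
#'
#' @param x a [PanelCountSet-class].
#' @return integer matrix of raw probe counts.
#' @export
panelCounts <- function(x) assay(x, "counts")

#' Normalized counts of a PanelCountSet
#'
#' Available after [normalizeCounts()]; errors otherwise.
#' @param x a [PanelCountSet-class] returned by [normalizeCounts()].
#' @return numeric matrix of normalized counts.
#' @export
normalizedCounts <- function(x) {
  if (!"normalized" %in% assayNames(x))
    stop("no 'normalized' assay; run normalizeCounts() first")
  assay(x, "normalized")
}

#' Normalization model attached to a normalized PanelCountSet
#'
#' @param x a [PanelCountSet-class] returned by [normalizeCounts()].
#' @return the [NormalizationModel-class] recorded during normalization.
#' @export
normalizationModel <- function(x) {
  m <- metadata(x)$normalization
  if (is.null(m)) stop("no normalization model; run normalizeCounts() first")
  m
}

#' Log2 ratio matrix of a PanelRatios object
#'
#' @param x a [PanelRatios-class].
#' @return numeric matrix of log2 ratios (genes x samples).
#' @export
log2Ratios <- function(x) assay(x, "log2ratio")

#' Batch-to-reference map of a PanelRatios object
#'
#' @param x a [PanelRatios-class].
#' @return named character vector, batch id -> reference sample id.
#' @export
referenceMap <- function(x) metadata(x)$referenceMap

#' Sample metadata as a data.frame
#'
#' @param x a [PanelCountSet-class] or [PanelRatios-class].
#' @return data.frame with one row per sample (reference samples included).
#' @export
sampleInfo <- function(x) {
  cd <- as.data.frame(colData(x))
  cd$sample_id <- rownames(cd)
  cd[, c("sample_id", setdiff(colnames(cd), "sample_id")), drop = FALSE]
}

#' Selected housekeeping genes of a GeNormResult
#'
#' @param x a [GeNormResult-class].
#' @return character vector of selected reference genes.
#' @export
selectedHousekeepers <- function(x) x@selected

#' geNorm stability M values
#'
#' @param x a [GeNormResult-class].
#' @return named numeric vector of final-round M values.
#' @export
mValues <- function(x) x@mValues

#' geNorm pairwise-variation series V(n/n+1)
#'
#' @param x a [GeNormResult-class].
#' @return named numeric vector keyed "n/n+1".
#' @export
vSeries <- function(x) x@vSeries
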