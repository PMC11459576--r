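#' Per-site regulator call matrix for one patient
#'
#' Collects, for one patient with samples from at least two tissue sites,
#' the regulator log2 ratios, high-expression calls and dominant label per
#' site. Duplicate site labels are suffixed (`liver`, `liver.2`, ...).
#'
#' @param ratios a [PanelRatios-class] whose `colData` carries `PatientID`
#'   and `TissueSite`.
#' @param patientId patient identifier.
#' @param cutoff high-expression cutoff (default 1.0).
#' @param genes gene set to track (default [sclcRegulators]).
#' @return list of class `siteCallMatrix`: `patient_id`, `sites`,
#'   `ratio` (site x gene matrix), `high` (logical site x gene matrix),
#'   `dominant` (named character per site).
#' @export
siteCallMatrix <- function(ratios, patientId, cutoff = 1.0,
                           genes = sclcRegulators) {
  stopifnot(is(ratios, "PanelRatios"))
  missing <- setdiff(genes, rownames(ratios))
  if (length(missing))
    stop("gene(s) absent from the ratio matrix: ",
         paste(missing, collapse = ", "))
  cd <- colData(ratios)
  sel <- !cd$IsReference & !is.na(cd$PatientID) & cd$PatientID == patientId
  if (sum(sel) < 2)
    stop("patient ", patientId,
         " needs at least two non-reference samples from distinct sites")
  cols <- colnames(ratios)[sel]
  sites <- as.character(cd$TissueSite[sel])
  if (anyNA(sites)) stop("tissue_site missing for patient ", patientId)
  if (length(unique(sites)) < 2)
    stop("patient ", patientId, " needs samples from at least two sites")
  sites <- make.unique(sites, sep = ".")

  mat <- t(log2Ratios(ratios)[genes, cols, drop = FALSE])
  rownames(mat) <- sites
  high <- callHigh(mat, cutoff)
  dim(high) <- dim(mat); dimnames(high) <- dimnames(mat)
  dominant <- vapply(seq_along(sites), function(i)
    dominantRegulator(mat[i, ], cutoff,
                      regulators = intersect(sclcRegulators, genes)),
    character(1))
  names(dominant) <- sites
  structure(list(patient_id = patientId, sites = sites, ratio = mat,
                 high = high, dominant = dominant),
            class = "siteCallMatrix")
}

#' Intra-patient discordance across tumor sites
#'
#' Summarizes intermetastatic heterogeneity for one patient: the genes
#' whose high/low call differs between sites, whether the dominant
#' regulator label switches between any two sites (NONE and TIE(...) count
#' as labels), and the pairwise Hamming distance between sites over the
#' tracked gene calls.
#'
#' @param matrix a `siteCallMatrix` from [siteCallMatrix()].
#' @return list of class `heterogeneityReport`: `patient_id`,
#'   `discordant_genes`, `switch`, `pairwise` (site x site integer matrix).
#' @export
discordance <- function(matrix) {
  stopifnot(inherits(matrix, "siteCallMatrix"))
  high <- matrix$high
  disc <- colnames(high)[apply(high, 2, function(v) any(v) && !all(v))]
  switch <- length(unique(matrix$dominant)) > 1
  nS <- nrow(high)
  pw <- vapply(seq_len(nS), function(i)
    vapply(seq_len(nS), function(j)
      sum(high[i, ] != high[j, ]), integer(1)), integer(nS))
  dimnames(pw) <- list(rownames(high), rownames(high))
  structure(list(patient_id = matrix$patient_id,
                 discordant_genes = disc, switch = switch, pairwise = pw),
            class = "heterogeneityReport")
}

#' @export
print.siteCallMatrix <- function(x, ...) {
  cat("siteCallMatrix for patient", x$patient_id, "-",
      length(x$sites), "sites x", ncol(x$ratio), "genes\n")
  cat("dominant:", paste(x$sites, x$dominant, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.heterogeneityReport <- function(x, ...) {
  cat("heterogeneityReport for patient", x$patient_id, "\n")
  cat("  discordant genes:",
      if (length(x$discordant_genes))
        paste(x$discordant_genes, collapse = ", ") else "(none)", "\n")
  cat("  dominant-subtype switch:", x$switch, "\n")
  invisible(x)
}
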