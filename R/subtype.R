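#' The SCLC transcription-regulator quartet
#'
#' Default regulator gene set used for subtyping: ASCL1 (SCLC-A), NEUROD1
#' (SCLC-N), POU2F3 (SCLC-P) and YAP1 (SCLC-Y).
#' @export
sclcRegulators <- c("ASCL1", "NEUROD1", "POU2F3", "YAP1")

#' High-expression call from a log2 ratio
#'
#' A gene is called "high" when its log2 ratio against the universal
#' reference is greater than or equal to the cutoff (inclusive). The
#' working cutoff is 1.0; the stricter assay-validation cutoff of 2.0
#' remains available through the `cutoff` argument.
#'
#' @param ratio numeric log2 ratio(s); must be finite.
#' @param cutoff log2-ratio cutoff (default 1.0).
#' @return logical vector.
#' @examples
#' callHigh(1.6)               # TRUE
#' callHigh(1.6, cutoff = 2)   # FALSE
#' @export
callHigh <- function(ratio, cutoff = 1.0) {
  if (any(!is.finite(ratio))) stop("log2 ratio must be finite")
  ratio >= cutoff
}

#' Dominant transcription regulator of one sample
#'
#' The dominant regulator is the quartet gene with the highest log2 ratio,
#' provided that maximum reaches the high-expression cutoff; otherwise the
#' label is `"NONE"`. Exact ties among maxima at or above the cutoff are
#' reported as `"TIE(g1,g2,...)"` rather than silently broken.
#'
#' @param ratios named numeric vector containing a log2 ratio for each of
#'   the four regulators.
#' @param cutoff high-expression cutoff (default 1.0).
#' @param regulators regulator gene set (default [sclcRegulators]).
#' @return a single character label: a gene name, `"NONE"`, or `"TIE(...)"`.
#' @export
dominantRegulator <- function(ratios, cutoff = 1.0,
                              regulators = sclcRegulators) {
  missing <- setdiff(regulators, names(ratios))
  if (length(missing))
    stop("missing regulator ratio(s): ", paste(missing, collapse = ", "))
  r <- ratios[regulators]
  if (any(!is.finite(r))) stop("regulator ratios must be finite")
  mx <- max(r)
  if (mx < cutoff) return("NONE")
  top <- regulators[r == mx]
  if (length(top) > 1) paste0("TIE(", paste(top, collapse = ","), ")")
  else top
}

#' Multi-marker profile label
#'
#' Counts how many of the regulator quartet are called high:
#' 0 -> NONE_HIGH, 1 -> SINGLE, 2 -> DOUBLE, 3 -> TRIPLE, 4 -> QUAD.
#'
#' @param highRegulators character vector, the regulators called high.
#' @param regulators the admissible quartet (default [sclcRegulators]).
#' @return one of `"NONE_HIGH"`, `"SINGLE"`, `"DOUBLE"`, `"TRIPLE"`,
#'   `"QUAD"`.
#' @export
profileLabel <- function(highRegulators, regulators = sclcRegulators) {
  outside <- setdiff(highRegulators, regulators)
  if (length(outside))
    stop("gene(s) outside the regulator set: ",
         paste(outside, collapse = ", "))
  c("NONE_HIGH", "SINGLE", "DOUBLE", "TRIPLE",
    "QUAD")[length(unique(highRegulators)) + 1]
}

#' Subtype every sample of a cohort
#'
#' Converts a [PanelRatios-class] into per-sample calls: the regulator
#' ratios, the set of all panel genes called high, the dominant regulator
#' and the multi-marker profile. Universal-reference samples are excluded
#' unless `includeReference = TRUE`.
#'
#' @param ratios a [PanelRatios-class].
#' @param cutoff high-expression log2-ratio cutoff (default 1.0).
#' @param regulators regulator gene set (default [sclcRegulators]).
#' @param includeReference keep reference samples (default FALSE).
#' @return data.frame with one row per sample: `sample_id`, one ratio
#'   column per regulator, `high_genes` (comma-separated, panel order),
#'   `n_high`, `dominant`, `profile`.
#' @examples
#' sim <- simulateCohort(simConfig(n_samples = 6, seed = 3))
#' r <- ratiosToReference(normalizeCounts(sim$counts))
#' callSubtypes(r)
#' @export
callSubtypes <- function(ratios, cutoff = 1.0, regulators = sclcRegulators,
                         includeReference = FALSE) {
  stopifnot(is(ratios, "PanelRatios"))
  missing <- setdiff(regulators, rownames(ratios))
  if (length(missing))
    stop("regulator(s) absent from the ratio matrix: ",
         paste(missing, collapse = ", "))
  mat <- log2Ratios(ratios)
  keep <- if (includeReference) colnames(mat)
          else colnames(mat)[!colData(ratios)$IsReference]
  rows <- lapply(keep, function(s) {
    r <- mat[, s]
    high <- rownames(mat)[callHigh(r, cutoff)]
    regHigh <- intersect(regulators, high)
    out <- data.frame(sample_id = s, stringsAsFactors = FALSE)
    for (g in regulators) out[[g]] <- unname(r[g])
    out$high_genes <- paste(high, collapse = ",")
    out$n_high <- length(high)
    out$dominant <- dominantRegulator(r[regulators], cutoff, regulators)
    out$profile <- profileLabel(regHigh, regulators)
    out
  })
  do.call(rbind, rows)
}

#' Cohort-level subtype summary
#'
#' Exact counting over a set of per-sample calls: prevalence of high
#' expression per regulator, dominant-label counts (all `TIE(...)` labels
#' pooled under `TIE`) and profile counts. Percentages are rendered with
#' [formatPercent()].
#'
#' @param calls data.frame from [callSubtypes()].
#' @param regulators regulator gene set (default [sclcRegulators]).
#' @param cutoff high-expression cutoff used for prevalence (default 1.0).
#' @param percentMode `"half_up"` (default) or `"truncate"`.
#' @return list with `n`, `prevalence_high` (fractions), `prevalence_pct`,
#'   `dominant_counts`, `profile_counts`.
#' @export
subtypeCohortSummary <- function(calls, regulators = sclcRegulators,
                                 cutoff = 1.0,
                                 percentMode = c("half_up", "truncate")) {
  if (!is.data.frame(calls) || nrow(calls) == 0)
    stop("need a nonempty data.frame of subtype calls")
  percentMode <- match.arg(percentMode)
  n <- nrow(calls)
  prevalence <- vapply(regulators,
                       function(g) sum(callHigh(calls[[g]], cutoff)) / n,
                       numeric(1))
  domLabel <- ifelse(grepl("^TIE\\(", calls$dominant), "TIE", calls$dominant)
  domLevels <- c(regulators, "NONE", "TIE")
  dominant <- table(factor(domLabel, levels = domLevels))
  profLevels <- c("NONE_HIGH", "SINGLE", "DOUBLE", "TRIPLE", "QUAD")
  profile <- table(factor(calls$profile, levels = profLevels))
  list(
    n = n,
    prevalence_high = prevalence,
    prevalence_pct = formatPercent(prevalence, mode = percentMode),
    dominant_counts = dominant,
    profile_counts = profile
  )
}
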