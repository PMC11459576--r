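# histology-group helpers ----------------------------------------------------

groupColumns <- function(ratios, group) {
  cd <- colData(ratios)
  hist <- as.character(cd$Histology)
  if (!group %in% hist[!is.na(hist)])
    stop("unknown histology group: ", group)
  cols <- colnames(ratios)[!cd$IsReference & !is.na(hist) & hist == group]
  if (length(cols) == 0)
    stop("no non-reference samples in group ", group)
  cols
}

#' Screen for genes with high mean expression in a group
#'
#' Returns the genes whose arithmetic mean log2 ratio over the group's
#' samples (reference samples excluded) is at or above `threshold`, sorted
#' by mean descending.
#'
#' @param ratios a [PanelRatios-class].
#' @param group histology label (matched against `colData()$Histology`).
#' @param threshold mean log2-ratio threshold (default 1.0).
#' @return data.frame with columns `gene`, `mean_log2`, `n`.
#' @export
highMeanScreen <- function(ratios, group, threshold = 1.0) {
  cols <- groupColumns(ratios, group)
  m <- rowMeans(log2Ratios(ratios)[, cols, drop = FALSE])
  hit <- m[m >= threshold]
  hit <- hit[order(-hit)]
  data.frame(gene = names(hit), mean_log2 = unname(hit),
             n = length(cols), row.names = NULL)
}

#' Prevalence of high expression of one gene in a group
#'
#' @param ratios a [PanelRatios-class].
#' @param group histology label.
#' @param gene gene identifier.
#' @param cutoff high-expression log2-ratio cutoff (default 1.0, inclusive,
#'   consistent with subtyping).
#' @return list with `count`, `n`, `fraction`.
#' @export
prevalenceHigh <- function(ratios, group, gene, cutoff = 1.0) {
  if (!gene %in% rownames(ratios))
    stop("gene absent from the ratio matrix: ", gene)
  cols <- groupColumns(ratios, group)
  r <- log2Ratios(ratios)[gene, cols]
  count <- sum(callHigh(r, cutoff))
  list(count = count, n = length(cols), fraction = count / length(cols))
}

#' Per-gene differential expression between two histology groups
#'
#' Two-sided test per gene on log2 ratios (Mann-Whitney U by default,
#' Welch t as an option), Benjamini-Hochberg adjustment across all tested
#' genes, and a direction from the group medians.
#'
#' @param ratios a [PanelRatios-class].
#' @param groupA,groupB histology labels.
#' @param method `"mann_whitney"` (default) or `"welch_t"`.
#' @param minPerGroup minimum samples per group (default 3).
#' @return data.frame with `gene`, `statistic`, `p`, `q`, `median_a`,
#'   `median_b`, `direction` (`higher_in_a` / `higher_in_b` / `ns`, from
#'   the group medians).
#' @export
differentialByGroup <- function(ratios, groupA, groupB,
                                method = c("mann_whitney", "welch_t"),
                                minPerGroup = 3) {
  method <- match.arg(method)
  colsA <- groupColumns(ratios, groupA)
  colsB <- groupColumns(ratios, groupB)
  if (length(colsA) < minPerGroup || length(colsB) < minPerGroup)
    stop("each group needs at least ", minPerGroup, " samples")
  mat <- log2Ratios(ratios)
  res <- lapply(rownames(mat), function(g) {
    a <- mat[g, colsA]; b <- mat[g, colsB]
    ht <- if (method == "mann_whitney")
      suppressWarnings(wilcox.test(a, b, exact = FALSE))
    else t.test(a, b)
    ma <- median(a); mb <- median(b)
    data.frame(gene = g, statistic = unname(ht$statistic), p = ht$p.value,
               median_a = ma, median_b = mb,
               direction = if (ma > mb) "higher_in_a"
                           else if (ma < mb) "higher_in_b" else "ns")
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("gene", "statistic", "p", "q",
          "median_a", "median_b", "direction")]
}

#' Correlation between two genes within a group
#'
#' Spearman (default) or Pearson correlation of two genes' log2 ratios
#' across the samples of one histology group; used e.g. for the immune
#' checkpoint panel (LAG3 vs PDCD1/CTLA4/TIGIT).
#'
#' @param ratios a [PanelRatios-class].
#' @param group histology label.
#' @param geneA,geneB gene identifiers.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r`, `p`, `n` (see [correlatePaired()]).
#' @export
genePairCorrelation <- function(ratios, group, geneA, geneB,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  missing <- setdiff(c(geneA, geneB), rownames(ratios))
  if (length(missing))
    stop("gene(s) absent from the ratio matrix: ",
         paste(missing, collapse = ", "))
  cols <- groupColumns(ratios, group)
  mat <- log2Ratios(ratios)
  correlatePaired(mat[geneA, cols], mat[geneB, cols], method = method)
}
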