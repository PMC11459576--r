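#' Binarize an IHC H-score
#'
#' An H-score (0-300) is called positive when it is strictly greater than
#' the cutoff (default 10). Note the asymmetry with panel calls: protein
#' positivity is strict ">", RNA high-expression is inclusive ">=".
#'
#' @param hScore integer H-score(s) in \[0, 300\].
#' @param cutoff positivity cutoff (default 10).
#' @return logical vector.
#' @export
binarizeIhc <- function(hScore, cutoff = 10) {
  if (any(!is.finite(hScore)) || any(hScore < 0) || any(hScore > 300))
    stop("H-scores must lie in [0, 300]")
  hScore > cutoff
}

#' Cross-tabulate test calls against reference calls
#'
#' Builds the 2x2 agreement table between a test method (the panel
#' high-call) and a reference method (e.g. IHC positivity). When both
#' vectors are named, they are aligned on shared sample ids and samples
#' missing from either side are dropped (the count is reported in the
#' `n_excluded` column); unnamed vectors must be equal length and aligned.
#'
#' @param test,reference logical vectors, optionally named by sample id.
#' @return one-row data.frame with columns `tp`, `fp`, `fn`, `tn`,
#'   `n_excluded`.
#' @export
agreementTable <- function(test, reference) {
  if (!is.null(names(test)) && !is.null(names(reference))) {
    shared <- intersect(names(test), names(reference))
    excluded <- length(union(names(test), names(reference))) - length(shared)
    if (length(shared) == 0) stop("no overlapping samples")
    test <- test[shared]
    reference <- reference[shared]
  } else {
    if (length(test) != length(reference))
      stop("unnamed call vectors must have equal length")
    if (length(test) == 0) stop("no overlapping samples")
    excluded <- 0L
  }
  ok <- !is.na(test) & !is.na(reference)
  excluded <- excluded + sum(!ok)
  test <- test[ok]; reference <- reference[ok]
  if (length(test) == 0) stop("no overlapping samples")
  data.frame(
    tp = sum(test & reference), fp = sum(test & !reference),
    fn = sum(!test & reference), tn = sum(!test & !reference),
    n_excluded = excluded
  )
}

#' Wilson 95% score interval for a proportion
#'
#' @param x successes, `n` trials, `conf` confidence level.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lo, hi)` on the \[0, 1\] scale.
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Agreement metrics from one or more 2x2 tables
#'
#' Computes PPA (positive percent agreement, sensitivity analog),
#' NPA (negative percent agreement, specificity analog), PPV, NPV and OPA
#' (overall percent agreement) from 2x2 agreement tables, each with a 95%
#' Wilson score interval. Multiple tables (e.g. one per marker) are pooled
#' by summing cells first — never by averaging per-table percentages. A
#' metric whose denominator is zero is not assessable and is reported as
#' `NA`, never as 0 or 100.
#'
#' @param tables data.frame with columns `tp`, `fp`, `fn`, `tn`; one row
#'   per marker (rows are pooled).
#' @param conf confidence level for the Wilson intervals (default 0.95).
#' @return data.frame with columns `metric`, `numerator`, `denominator`,
#'   `estimate` (percentage or NA), `lo`, `hi`.
#' @examples
#' agreementMetrics(data.frame(tp = 9, fp = 1, fn = 0, tn = 2))
#' @export
agreementMetrics <- function(tables, conf = 0.95) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% colnames(tables))) stop("tables need tp/fp/fn/tn")
  tp <- sum(tables$tp); fp <- sum(tables$fp)
  fn <- sum(tables$fn); tn <- sum(tables$tn)
  n <- tp + fp + fn + tn
  if (n < 1) stop("empty agreement table")
  cells <- list(
    PPA = c(tp, tp + fn), NPA = c(tn, tn + fp),
    PPV = c(tp, tp + fp), NPV = c(tn, tn + fn),
    OPA = c(tp + tn, n)
  )
  rows <- lapply(names(cells), function(m) {
    x <- cells[[m]][1]; d <- cells[[m]][2]
    if (d == 0)
      return(data.frame(metric = m, numerator = x, denominator = d,
                        estimate = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- wilsonInterval(x, d, conf)
    data.frame(metric = m, numerator = x, denominator = d,
               estimate = 100 * x / d,
               lo = 100 * ci[["lo"]], hi = 100 * ci[["hi"]])
  })
  do.call(rbind, rows)
}

#' Correlation between paired measurements
#'
#' Pearson or Spearman correlation between two aligned vectors, optionally
#' after a log2(v + pseudo) transform of both sides (for comparing linear
#' panel counts with RNA-Seq TPM on the log scale). Degenerate input —
#' fewer than three finite pairs or zero variance on either side — raises
#' an error rather than returning a silent NaN.
#'
#' @param x,y aligned numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"none"` (default; inputs used as-is, e.g. log2 ratios)
#'   or `"log2"` (both sides transformed as log2(v + pseudo)).
#' @param pseudo pseudo-count for the log2 transform (default 0.5).
#' @return list with `r`, `p`, `n`, `method`, `transform`.
#' @export
correlatePaired <- function(x, y, method = c("pearson", "spearman"),
                            transform = c("none", "log2"), pseudo = 0.5) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (length(x) != length(y)) stop("x and y must be aligned")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least three finite pairs")
  if (transform == "log2") {
    if (any(x < 0) || any(y < 0)) stop("log2 transform needs values >= 0")
    x <- log2(x + pseudo); y <- log2(y + pseudo)
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: zero variance in at least one vector")
  ct <- suppressWarnings(
    cor.test(x, y, method = method, alternative = "two.sided", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method, transform = transform)
}
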