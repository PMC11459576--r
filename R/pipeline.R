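#' Validate a pipeline configuration
#'
#' Fail-fast validation of the whole configuration before any stage runs:
#' referenced files must exist, parameters must lie in their documented
#' ranges, and enabled optional stages must have their inputs.
#'
#' @param config list (or path to a YAML file) with entries:
#'   `counts`/`panel`/`sheet` (input paths) or `simulate` (a list of
#'   [simConfig()] arguments); `out_dir`; optional `ihc` (IHC table path,
#'   enables concordance), `cutoff` (default 1), `k_sd` (default 2),
#'   `v_threshold` (default 0.15), `min_housekeepers` (default 3),
#'   `pseudo_count` (default 0.5), `regulators`, `seed` (default 1).
#' @return the normalized config list, with defaults filled in.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(cutoff = 1.0, k_sd = 2, v_threshold = 0.15,
                   min_housekeepers = 3, pseudo_count = 0.5,
                   regulators = sclcRegulators, seed = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  hasFiles <- !is.null(config$counts)
  hasSim <- !is.null(config$simulate)
  if (!hasFiles && !hasSim)
    stop("config needs either 'counts'/'panel'/'sheet' paths or 'simulate'")
  if (hasFiles) {
    for (k in c("counts", "panel", "sheet"))
      if (is.null(config[[k]]) || !file.exists(config[[k]]))
        stop("config input missing or not found: ", k)
  }
  if (!is.null(config$ihc) && !file.exists(config$ihc))
    stop("IHC table enabled but file not found: ", config$ihc)
  if (config$cutoff < 0 || config$v_threshold <= 0 ||
      config$min_housekeepers < 2 || config$k_sd < 0 ||
      config$pseudo_count <= 0)
    stop("pipeline parameter out of range")
  config
}

#' Run the full panel pipeline
#'
#' Executes the fixed stage order counts -> normalization -> log2 ratios ->
#' subtype calls -> cohort summary (-> IHC concordance when an IHC table is
#' configured), writing deterministic TSV reports and a YAML manifest
#' (package version, config hash, per-stage row counts) to `out_dir`.
#' Any stage error aborts the run and removes partial outputs.
#'
#' @param config list or YAML path, see [validatePipelineConfig()].
#' @return the manifest list, invisibly; outputs land in `config$out_dir`.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(config$out_dir,
                       c("ratios.tsv", "calls.tsv", "summary.tsv",
                         "concordance.tsv", "manifest.yaml"))
  names(outputs) <- c("ratios", "calls", "summary", "concordance",
                      "manifest")
  cleanup <- function() unlink(outputs[file.exists(outputs)])

  manifest <- tryCatch({
    msg <- function(stage) message("[stage] ", stage)
    msg("input")
    pcs <- if (!is.null(config$counts))
      readCountTable(config$counts, config$panel, config$sheet)
    else {
      simArgs <- config$simulate
      simArgs$seed <- config$seed
      simulateCohort(do.call(simConfig, simArgs))$counts
    }

    msg("normalize")
    norm <- normalizeCounts(pcs, kSd = config$k_sd,
                            vThreshold = config$v_threshold,
                            minHousekeepers = config$min_housekeepers)

    msg("ratios")
    ratios <- ratiosToReference(norm, pseudoCount = config$pseudo_count)
    ratioTab <- data.frame(gene = rownames(ratios),
                           log2Ratios(ratios), check.names = FALSE)
    writeReport(ratioTab, outputs["ratios"])

    msg("subtype")
    calls <- callSubtypes(ratios, cutoff = config$cutoff,
                          regulators = config$regulators)
    writeReport(calls, outputs["calls"])
    summary <- subtypeCohortSummary(calls, regulators = config$regulators,
                                    cutoff = config$cutoff)
    sumTab <- data.frame(
      metric = c(paste0("prevalence_pct_", config$regulators),
                 paste0("dominant_n_", names(summary$dominant_counts)),
                 paste0("profile_n_", names(summary$profile_counts))),
      value = c(summary$prevalence_pct,
                as.numeric(summary$dominant_counts),
                as.numeric(summary$profile_counts))
    )
    writeReport(sumTab, outputs["summary"])

    rowCounts <- list(samples = ncol(pcs), genes = nrow(pcs),
                      calls = nrow(calls))

    if (!is.null(config$ihc)) {
      msg("concordance")
      ihc <- readIhcTable(config$ihc)
      markers <- intersect(config$regulators, unique(ihc$marker))
      tabs <- lapply(markers, function(m) {
        sub <- ihc[ihc$marker == m, ]
        ref <- setNames(binarizeIhc(sub$h_score), sub$sample_id)
        test <- setNames(callHigh(calls[[m]], config$cutoff),
                         calls$sample_id)
        agreementTable(test, ref)
      })
      tabAll <- do.call(rbind, tabs)
      perMarker <- do.call(rbind, lapply(seq_along(markers), function(i) {
        m <- agreementMetrics(tabs[[i]])
        data.frame(marker = markers[i], tabs[[i]][, c("tp", "fp", "fn", "tn")],
                   metric = m$metric, estimate = m$estimate,
                   lo = m$lo, hi = m$hi)
      }))
      pooled <- agreementMetrics(tabAll)
      concTab <- rbind(perMarker,
                       data.frame(marker = "POOLED",
                                  tp = sum(tabAll$tp), fp = sum(tabAll$fp),
                                  fn = sum(tabAll$fn), tn = sum(tabAll$tn),
                                  metric = pooled$metric,
                                  estimate = pooled$estimate,
                                  lo = pooled$lo, hi = pooled$hi))
      colnames(concTab)[colnames(concTab) == "estimate"] <- "estimate_pct"
      colnames(concTab)[colnames(concTab) == "lo"] <- "ci_lo_pct"
      colnames(concTab)[colnames(concTab) == "hi"] <- "ci_hi_pct"
      writeReport(concTab, outputs["concordance"])
      rowCounts$concordance <- nrow(concTab)
    }

    cfgForHash <- config[order(names(config))]
    cfgForHash$out_dir <- NULL
    manifest <- list(
      package = "sclcpanel",
      version = as.character(packageVersion("sclcpanel")),
      config_hash = fnv1aHash(yaml::as.yaml(cfgForHash)),
      seed = config$seed,
      rows = rowCounts
    )
    yaml::write_yaml(manifest, outputs["manifest"])
    manifest
  }, error = function(e) {
    cleanup()
    stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
  })
  invisible(manifest)
}
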