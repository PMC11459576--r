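#' Default 204-gene panel definition
#'
#' A synthetic panel definition with the structure a targeted SCLC
#' hybridization-counting panel presumes: 204 endogenous targets (the
#' regulator quartet, common SCLC and immune markers, plus generic filler
#' genes), 8 housekeeping genes, a 6-probe positive-control concentration
#' ladder and 8 negative controls. Baselines (reference-sample expected
#' counts) are fixed deterministic values spread over 400-2000 counts.
#'
#' @param nEndogenous number of endogenous genes (default 204).
#' @return data.frame with columns `gene`, `code_class`, `nominal_conc`,
#'   `baseline`.
#' @export
defaultPanel <- function(nEndogenous = 204) {
  named <- c("ASCL1", "NEUROD1", "POU2F3", "YAP1", "DLL3", "EZH2", "TERT",
             "RET", "MYC", "CDKN2A", "LAG3", "PDCD1", "CTLA4", "TIGIT",
             "CD274", "INSM1", "EGFR", "ERBB2", "MET", "ROS1")
  if (nEndogenous < length(named))
    stop("nEndogenous must be at least ", length(named))
  filler <- sprintf("GENE%03d", seq_len(nEndogenous - length(named)))
  endo <- c(named, filler)
  hk <- c("ACTB", "GAPDH", "B2M", "GUSB", "HPRT1", "PGK1", "RPLP0", "TBP")
  ladder <- c(128, 32, 8, 2, 0.5, 0.125)
  pos <- paste0("POS_", LETTERS[seq_along(ladder)])
  neg <- paste0("NEG_", LETTERS[1:8])
  panel <- data.frame(
    gene = c(endo, hk, pos, neg),
    code_class = c(rep("Endogenous", length(endo)),
                   rep("Housekeeping", length(hk)),
                   rep("Positive", length(pos)),
                   rep("Negative", length(neg))),
    nominal_conc = c(rep(NA_real_, length(endo) + length(hk)),
                     ladder, rep(NA_real_, length(neg))),
    stringsAsFactors = FALSE
  )
  # deterministic baselines, divisible by 4 so integer counts survive
  # fold changes of 2^2 and 2^-1 in the noiseless limit
  nGenes <- nrow(panel)
  panel$baseline <- 400 * (1 + (seq_len(nGenes) - 1) %% 5)
  panel$baseline[panel$code_class == "Positive"] <- NA_real_
  panel$baseline[panel$code_class == "Negative"] <- NA_real_
  panel
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-cohort
#' generator. Defaults emulate a small clinical SCLC cohort: 35 tumor
#' samples in 4 batches, subtype proportions close to the dominant-label
#' mix reported for clinical SCLC cohorts (ASCL1 0.74, NEUROD1 0.20,
#' POU2F3 0.03, none 0.03), a 3 log2-unit separation between high and low
#' regulator means, negative-binomial counts with dispersion 0.1, lognormal
#' lane size factors (SD 0.2 on the log scale), low-noise housekeepers and
#' Poisson negative-control background.
#'
#' @param n_samples tumor samples (reference samples are added per batch).
#' @param n_batches number of batches/runs (default 4).
#' @param panel panel definition with baselines (default [defaultPanel()]).
#' @param subtype_props named probabilities over `ASCL1`, `NEUROD1`,
#'   `POU2F3`, `YAP1`, `none` (missing names get 0); must sum to 1.
#' @param regulator_high_mean,regulator_low_mean,regulator_sd log2-scale
#'   mean/SD of the subtype's high regulator vs the other regulators
#'   (defaults 2.0, -1.0, 0.5).
#' @param other_sd log2 SD of biological noise on non-regulator endogenous
#'   genes around a true ratio of 0 (default 0.3).
#' @param nb_dispersion negative-binomial dispersion of endogenous and
#'   housekeeping counts; 0 means deterministic counts (default 0.1).
#' @param lane_size_sd SD of the log lane size factor (default 0.2).
#' @param hk_sd log2 SD of housekeeping biological noise (default 0.1).
#' @param neg_mean Poisson mean of negative-control counts (default 5).
#' @param pos_scale counts per fM for the positive ladder (default 200, so
#'   the faintest 0.125 fM probe sits well above background).
#' @param couple_dll3 make DLL3 follow the ASCL1 high/low state, mirroring
#'   its ASCL1-regulated biology (default TRUE).
#' @param ihc_slope,ihc_noise H-score link: slope on the linear fold-change
#'   excess and Gaussian noise SD (defaults 50, 10).
#' @param tpm_intercept,tpm_noise log2-TPM link: intercept and Gaussian
#'   noise SD around slope 1 (defaults 4, 0.3).
#' @param seed integer RNG seed.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(n_samples = 35, n_batches = 4, panel = defaultPanel(),
                      subtype_props = c(ASCL1 = 0.74, NEUROD1 = 0.20,
                                        POU2F3 = 0.03, YAP1 = 0, none = 0.03),
                      regulator_high_mean = 2.0, regulator_low_mean = -1.0,
                      regulator_sd = 0.5, other_sd = 0.3,
                      nb_dispersion = 0.1, lane_size_sd = 0.2, hk_sd = 0.1,
                      neg_mean = 5, pos_scale = 200, couple_dll3 = TRUE,
                      ihc_slope = 50, ihc_noise = 10,
                      tpm_intercept = 4, tpm_noise = 0.3, seed = 1) {
  labels <- c("ASCL1", "NEUROD1", "POU2F3", "YAP1", "none")
  props <- setNames(rep(0, length(labels)), labels)
  props[names(subtype_props)] <- subtype_props
  if (abs(sum(props) - 1) > 1e-8) stop("subtype_props must sum to 1")
  if (n_samples < 1 || n_batches < 1) stop("need >= 1 sample and batch")
  if (n_batches > n_samples) stop("more batches than tumor samples")
  sds <- c(regulator_sd, other_sd, lane_size_sd, hk_sd,
           ihc_noise, tpm_noise)
  if (any(sds < 0) || nb_dispersion < 0 || neg_mean < 0)
    stop("noise parameters must be >= 0")
  if (regulator_high_mean <= regulator_low_mean)
    stop("regulator_high_mean must exceed regulator_low_mean")
  cfg <- list(
    n_samples = as.integer(n_samples), n_batches = as.integer(n_batches),
    panel = panel, subtype_props = props,
    regulator_high_mean = regulator_high_mean,
    regulator_low_mean = regulator_low_mean,
    regulator_sd = regulator_sd, other_sd = other_sd,
    nb_dispersion = nb_dispersion, lane_size_sd = lane_size_sd,
    hk_sd = hk_sd, neg_mean = neg_mean, pos_scale = pos_scale,
    couple_dll3 = couple_dll3, ihc_slope = ihc_slope, ihc_noise = ihc_noise,
    tpm_intercept = tpm_intercept, tpm_noise = tpm_noise,
    seed = as.integer(seed)
  )
  structure(cfg, class = "SimConfig")
}

#' Noise-free simulation configuration
#'
#' Convenience wrapper: all noise terms (regulator/housekeeping/lane SDs,
#' count dispersion, Poisson background, link noise) set to zero, so the
#' end-to-end pipeline recovers the simulated truth exactly (the background
#' floor is inactive because all negative controls are zero).
#'
#' @param ... overrides passed on to [simConfig()].
#' @return a `SimConfig`.
#' @export
noiselessConfig <- function(...) {
  simConfig(regulator_sd = 0, other_sd = 0, nb_dispersion = 0,
            lane_size_sd = 0, hk_sd = 0, neg_mean = 0,
            ihc_noise = 0, tpm_noise = 0, ...)
}

drawCounts <- function(mu, dispersion) {
  if (dispersion == 0) round(mu)
  else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a panel cohort with ground truth
#'
#' Generates raw counts for `n_samples` tumor samples plus one
#' universal-reference sample per batch. The reference lane's endogenous
#' means are the panel baselines; a tumor lane's endogenous mean is
#' `baseline * 2^(true log2 ratio) * lane factor`, drawn negative-binomial
#' at the configured dispersion (deterministic at dispersion 0). The
#' subtype's high regulator gets true ratio ~ N(high mean, regulator SD),
#' the remaining regulators ~ N(low mean, regulator SD), and other
#' endogenous genes ~ N(0, other SD). Housekeepers carry lognormal noise
#' only; positives are the noiseless ladder times the lane factor;
#' negatives are Poisson background. Each sample draws from its own RNG
#' stream keyed by (seed, sample index), so extending a cohort never
#' changes earlier samples.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return list with `counts` (a [PanelCountSet-class]) and `truth` (a
#'   list: `subtype`, `true_ratio` endogenous matrix over tumor samples,
#'   `lane_factor`, link parameters, `seed`).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  panel <- config$panel
  cc <- panel$code_class
  genes <- panel$gene
  endo <- genes[cc == "Endogenous"]
  hk <- genes[cc == "Housekeeping"]
  pos <- genes[cc == "Positive"]
  neg <- genes[cc == "Negative"]
  baseline <- setNames(panel$baseline, genes)
  ladder <- setNames(panel$nominal_conc[cc == "Positive"], pos)
  regs <- intersect(sclcRegulators, endo)

  nT <- config$n_samples
  batch <- paste0("B", rep_len(seq_len(config$n_batches), nT))
  tumorIds <- sprintf("S%03d", seq_len(nT))
  refIds <- setNames(paste0("REF_B", seq_len(config$n_batches)),
                     paste0("B", seq_len(config$n_batches)))

  sheet <- data.frame(
    sample_id = c(tumorIds, unname(refIds)),
    batch_id = c(batch, names(refIds)),
    patient_id = c(sprintf("P%03d", seq_len(nT)),
                   rep(NA_character_, length(refIds))),
    tissue_site = NA_character_,
    histology = c(rep("SCLC", nT), rep(NA_character_, length(refIds))),
    is_reference = c(rep(FALSE, nT), rep(TRUE, length(refIds))),
    tumor_pct = NA_real_,
    stringsAsFactors = FALSE
  )

  counts <- matrix(0L, nrow = length(genes), ncol = nrow(sheet),
                   dimnames = list(genes, sheet$sample_id))
  trueRatio <- matrix(NA_real_, nrow = length(endo), ncol = nT,
                      dimnames = list(endo, tumorIds))
  subtype <- setNames(character(nrow(sheet)), sheet$sample_id)
  laneFactor <- setNames(numeric(nrow(sheet)), sheet$sample_id)
  labels <- names(config$subtype_props)

  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    isRef <- sheet$is_reference[i]
    set.seed(sampleStreamSeed(config$seed, i))
    lane <- exp(rnorm(1, 0, config$lane_size_sd))
    laneFactor[sid] <- lane

    if (isRef) {
      subtype[sid] <- "reference"
      ratio <- setNames(rep(0, length(endo)), endo)
    } else {
      st <- sample(labels, 1, prob = config$subtype_props)
      subtype[sid] <- st
      ratio <- rnorm(length(endo), 0, config$other_sd)
      names(ratio) <- endo
      for (g in regs)
        ratio[g] <- rnorm(1,
          if (g == st) config$regulator_high_mean
          else config$regulator_low_mean,
          config$regulator_sd)
      if (config$couple_dll3 && "DLL3" %in% endo)
        ratio["DLL3"] <- rnorm(1,
          if (st == "ASCL1") config$regulator_high_mean
          else config$regulator_low_mean,
          config$regulator_sd)
      trueRatio[, sid] <- ratio
    }

    muEndo <- baseline[endo] * 2^ratio * lane
    counts[endo, sid] <- drawCounts(muEndo, config$nb_dispersion)
    muHk <- baseline[hk] * 2^rnorm(length(hk), 0, config$hk_sd) * lane
    counts[hk, sid] <- round(muHk)
    counts[pos, sid] <- round(ladder * config$pos_scale * lane)
    counts[neg, sid] <- rpois(length(neg), config$neg_mean)
  }

  pcs <- PanelCountSet(counts,
                       panel[, c("gene", "code_class", "nominal_conc")],
                       sheet)
  truth <- list(
    subtype = subtype, true_ratio = trueRatio, lane_factor = laneFactor,
    ihc_slope = config$ihc_slope, ihc_noise = config$ihc_noise,
    tpm_intercept = config$tpm_intercept, tpm_noise = config$tpm_noise,
    seed = config$seed
  )
  list(counts = pcs, truth = truth)
}

#' Simulate paired IHC H-scores from simulation truth
#'
#' H-score = clamp to \[0, 300\] of
#' `round(slope * max(0, 2^ratio - 1) + noise)`: zero in expectation for
#' genes at or below the reference level, monotone increasing in the true
#' expression above it.
#'
#' @param truth the `truth` element of [simulateCohort()] output.
#' @param markers gene identifiers to score (must be simulated genes).
#' @return data.frame with `sample_id`, `marker`, `h_score`.
#' @export
simulateIhc <- function(truth, markers = sclcRegulators) {
  missing <- setdiff(markers, rownames(truth$true_ratio))
  if (length(missing))
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  samples <- colnames(truth$true_ratio)
  set.seed(sampleStreamSeed(truth$seed, 100003))
  rows <- expand.grid(sample_id = samples, marker = markers,
                      stringsAsFactors = FALSE)
  r <- truth$true_ratio[cbind(rows$marker, rows$sample_id)]
  h <- round(truth$ihc_slope * pmax(0, 2^r - 1) +
               rnorm(nrow(rows), 0, truth$ihc_noise))
  rows$h_score <- as.integer(pmin(300, pmax(0, h)))
  rows
}

#' Simulate paired RNA-Seq TPM from simulation truth
#'
#' log2(TPM) = intercept + true log2 ratio + Gaussian noise; the slope of
#' the link is fixed at 1.
#'
#' @param truth the `truth` element of [simulateCohort()] output.
#' @param genes genes to quantify (default: all simulated endogenous).
#' @return numeric TPM matrix, genes x tumor samples.
#' @export
simulateRnaseq <- function(truth, genes = rownames(truth$true_ratio)) {
  missing <- setdiff(genes, rownames(truth$true_ratio))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  set.seed(sampleStreamSeed(truth$seed, 200003))
  r <- truth$true_ratio[genes, , drop = FALSE]
  lg <- truth$tpm_intercept + r +
    matrix(rnorm(length(r), 0, truth$tpm_noise), nrow(r), ncol(r))
  tpm <- 2^lg
  dimnames(tpm) <- dimnames(r)
  tpm
}
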