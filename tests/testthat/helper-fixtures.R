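# small panel: regulator quartet + DLL3 + one filler gene, 4 housekeepers,
# 3 positives, 3 negatives
toyPanel <- function() {
  data.frame(
    gene = c("ASCL1", "NEUROD1", "POU2F3", "YAP1", "DLL3", "GENE001",
             "HK1", "HK2", "HK3", "HK4",
             "POS_A", "POS_B", "POS_C",
             "NEG_A", "NEG_B", "NEG_C"),
    code_class = c(rep("Endogenous", 6), rep("Housekeeping", 4),
                   rep("Positive", 3), rep("Negative", 3)),
    nominal_conc = c(rep(NA, 10), 128, 32, 8, rep(NA, 3)),
    stringsAsFactors = FALSE
  )
}

toySheet <- function(ids, batch = "B1", ref = ids[length(ids)],
                     histology = "SCLC", patient = NA, site = NA) {
  data.frame(
    sample_id = ids,
    batch_id = batch,
    patient_id = patient,
    tissue_site = site,
    histology = ifelse(ids %in% ref, NA, histology),
    is_reference = ids %in% ref,
    tumor_pct = NA_real_,
    stringsAsFactors = FALSE
  )
}

# PanelCountSet with identical default lanes; override cells via `edits`,
# a list of list(gene=, sample=, count=)
toyCounts <- function(ids = c("S1", "S2", "REF"), ref = "REF",
                      edits = list(), batch = "B1") {
  panel <- toyPanel()
  base <- c(ASCL1 = 100, NEUROD1 = 100, POU2F3 = 100, YAP1 = 100,
            DLL3 = 100, GENE001 = 100,
            HK1 = 200, HK2 = 300, HK3 = 400, HK4 = 500,
            POS_A = 1024, POS_B = 256, POS_C = 64,
            NEG_A = 4, NEG_B = 6, NEG_C = 5)
  mat <- matrix(rep(base, length(ids)), ncol = length(ids),
                dimnames = list(panel$gene, ids))
  for (e in edits) mat[e$gene, e$sample] <- e$count
  PanelCountSet(mat, panel, toySheet(ids, batch = batch, ref = ref))
}

# build a PanelRatios directly from a ratio matrix (genes x samples)
makeRatios <- function(mat, histology = "SCLC", patient = NA,
                       site = NA, isReference = FALSE) {
  n <- ncol(mat)
  cd <- S4Vectors::DataFrame(
    BatchID = "B1",
    PatientID = rep_len(patient, n),
    TissueSite = rep_len(site, n),
    Histology = rep_len(histology, n),
    IsReference = rep_len(isReference, n),
    TumorPct = NA_real_,
    row.names = colnames(mat)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = mat), colData = cd)
  out <- new("PanelRatios", se)
  S4Vectors::metadata(out)$referenceMap <- c(B1 = NA_character_)
  out
}

# naive double-loop geNorm stability oracle, independent of the
# covariance-based implementation
naiveM <- function(logExpr) {
  g <- rownames(logExpr)
  vapply(g, function(j) {
    others <- setdiff(g, j)
    mean(vapply(others, function(k)
      stats::sd(logExpr[j, ] - logExpr[k, ]), numeric(1)))
  }, numeric(1))
}

# the four panel-vs-IHC 2x2 tables (12 samples per marker) uniquely
# reconstructible from the printed per-marker and pooled percentages
reconstructedTables <- function() {
  data.frame(
    marker = c("ASCL1", "NEUROD1", "POU2F3", "YAP1"),
    tp = c(9, 4, 1, 0),
    fp = c(1, 1, 0, 0),
    fn = c(0, 0, 1, 0),
    tn = c(2, 7, 10, 12)
  )
}

metricValue <- function(metrics, name) {
  metrics$estimate[metrics$metric == name]
}
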