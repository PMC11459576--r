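# RCC (Reporter Code Count) files are sectioned text: each section is
# bracketed as <Name> ... </Name>; Code_Summary holds the per-probe counts.
# Vendor exports vary between comma- and tab-delimited sections, may carry
# a BOM and CRLF line endings; all are accepted.

splitRccFields <- function(line) {
  if (grepl("\t", line)) strsplit(line, "\t", fixed = TRUE)[[1]]
  else strsplit(line, ",", fixed = TRUE)[[1]]
}

#' Read a NanoString-style RCC lane file
#'
#' Parses one Reporter Code Count file (one lane = one sample). Section
#' order is irrelevant; comma- and tab-delimited sections, BOM and CRLF
#' are all accepted.
#'
#' @param path path to an RCC file.
#' @return list with `counts` (data.frame: `CodeClass`, `Name`,
#'   `Accession`, `Count` integer) and `attributes` (named character,
#'   pooled from the Header/Sample_Attributes/Lane_Attributes sections).
#' @export
readRcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[1] <- sub("^\ufeff", "", lines[1])
  lines <- sub("\r$", "", lines)
  open <- grep("^<[^/][^>]*>\\s*$", lines)
  if (!length(open)) stop("not an RCC file (no bracketed sections): ", path)
  sections <- list()
  for (i in open) {
    name <- sub("^<([^>]*)>\\s*$", "\\1", lines[i])
    close <- grep(paste0("^</", name, ">\\s*$"), lines)
    close <- close[close > i][1]
    if (is.na(close)) stop("unterminated RCC section <", name, "> in ", path)
    sections[[name]] <- lines[(i + 1):(close - 1)]
  }
  if (!"Code_Summary" %in% names(sections))
    stop("RCC format error: missing Code_Summary section in ", path)

  body <- sections$Code_Summary
  body <- body[nzchar(trimws(body))]
  fields <- lapply(body, splitRccFields)
  header <- trimws(fields[[1]])
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% header))
    stop("RCC format error: Code_Summary needs columns ",
         paste(need, collapse = ", "))
  rows <- fields[-1]
  get <- function(row, col) trimws(row[match(col, header)])
  cnt <- vapply(rows, get, character(1), col = "Count")
  bad <- grepl("\\D", cnt) | !nzchar(cnt)
  if (any(bad))
    stop("non-integer Count in Code_Summary row for probe '",
         vapply(rows, get, character(1), col = "Name")[bad][1], "'")
  counts <- data.frame(
    CodeClass = vapply(rows, get, character(1), col = "CodeClass"),
    Name = vapply(rows, get, character(1), col = "Name"),
    Accession = vapply(rows, get, character(1), col = "Accession"),
    Count = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  attrSections <- intersect(c("Header", "Sample_Attributes",
                              "Lane_Attributes"), names(sections))
  attrs <- character()
  for (s in attrSections) {
    for (ln in sections[[s]]) {
      if (!nzchar(trimws(ln))) next
      kv <- splitRccFields(ln)
      if (length(kv) >= 1)
        attrs[trimws(kv[1])] <- if (length(kv) >= 2) trimws(kv[2]) else ""
    }
  }
  list(counts = counts, attributes = attrs)
}

#' Write one sample as an RCC lane file
#'
#' @param counts data.frame with columns `CodeClass`, `Name`, `Accession`,
#'   `Count` (integers).
#' @param path output path.
#' @param attributes optional named character vector written to the
#'   Sample_Attributes section (an `ID` entry is conventional).
#' @export
writeRcc <- function(counts, path, attributes = character()) {
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% colnames(counts)))
    stop("counts need columns ", paste(need, collapse = ", "))
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "",
    "<Sample_Attributes>",
    paste(names(attributes), unname(attributes), sep = ","),
    "</Sample_Attributes>",
    "",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste(counts$CodeClass, counts$Name, counts$Accession,
          as.integer(counts$Count), sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a panel definition file
#'
#' @param path TSV with columns `gene`, `code_class`, `nominal_conc`
#'   (`nominal_conc` may be empty except for Positive probes; an optional
#'   `baseline` column is kept when present).
#' @return data.frame panel definition.
#' @export
readPanel <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "code_class")
  if (!all(need %in% colnames(p)))
    stop("panel file needs columns ", paste(need, collapse = ", "))
  p$gene <- trimws(p$gene)
  if (anyDuplicated(p$gene)) stop("duplicate gene in panel definition")
  if (!"nominal_conc" %in% colnames(p)) p$nominal_conc <- NA_real_
  p$nominal_conc <- as.numeric(p$nominal_conc)
  p
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `batch_id`, `is_reference`
#'   and optionally `patient_id`, `tissue_site`, `histology`, `tumor_pct`.
#' @return data.frame sample sheet.
#' @export
readSampleSheet <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  need <- c("sample_id", "batch_id", "is_reference")
  if (!all(need %in% colnames(s)))
    stop("sample sheet needs columns ", paste(need, collapse = ", "))
  s$sample_id <- trimws(s$sample_id)
  s$is_reference <- as.logical(s$is_reference)
  if (anyNA(s$is_reference)) stop("is_reference must be TRUE/FALSE")
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in sheet")
  if ("histology" %in% colnames(s)) {
    bad <- setdiff(unique(s$histology[!is.na(s$histology)]),
                   c("SCLC", "LUAD", "SqCC", "Other"))
    if (length(bad))
      stop("unknown histology label(s): ", paste(bad, collapse = ", "))
  }
  s
}

#' Read a gene x sample count table with panel and sheet into a PanelCountSet
#'
#' @param path count table (TSV; first column gene ids, header sample ids).
#' @param panelPath panel definition TSV (see [readPanel()]).
#' @param sheetPath sample sheet TSV (see [readSampleSheet()]).
#' @return a validated [PanelCountSet-class].
#' @export
readCountTable <- function(path, panelPath, sheetPath) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE,
                    stringsAsFactors = FALSE)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "numeric"
  if (anyNA(mat)) stop("count table has missing or non-numeric cells")
  PanelCountSet(mat, readPanel(panelPath), readSampleSheet(sheetPath))
}

#' Assemble a PanelCountSet from a directory of RCC lane files
#'
#' Each RCC file is one lane/sample; sample ids come from the sheet and
#' are matched against the RCC `ID` sample attribute, falling back to the
#' file name without extension.
#'
#' @param dir directory containing `.RCC`/`.rcc` files.
#' @param panelPath,sheetPath as in [readCountTable()].
#' @return a validated [PanelCountSet-class].
#' @export
readRccDirectory <- function(dir, panelPath, sheetPath) {
  files <- list.files(dir, pattern = "\\.rcc$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no RCC files in ", dir)
  lanes <- lapply(files, readRcc)
  ids <- vapply(seq_along(lanes), function(i) {
    id <- lanes[[i]]$attributes["ID"]
    if (is.na(id) || !nzchar(id))
      sub("\\.rcc$", "", basename(files[i]), ignore.case = TRUE)
    else unname(id)
  }, character(1))
  genes <- lanes[[1]]$counts$Name
  mat <- vapply(lanes, function(l) {
    cnt <- setNames(l$counts$Count, l$counts$Name)
    if (!setequal(names(cnt), genes))
      stop("RCC files disagree on probe content")
    cnt[genes]
  }, numeric(length(genes)))
  dimnames(mat) <- list(genes, ids)
  PanelCountSet(mat, readPanel(panelPath), readSampleSheet(sheetPath))
}

#' Read a paired IHC H-score table
#'
#' @param path TSV with columns `sample_id`, `marker`, `h_score`.
#' @return data.frame with validated H-scores.
#' @export
readIhcTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "marker", "h_score")
  if (!all(need %in% colnames(x)))
    stop("IHC table needs columns ", paste(need, collapse = ", "))
  if (any(x$h_score < 0 | x$h_score > 300))
    stop("H-scores must lie in [0, 300]")
  if (anyDuplicated(x[, c("sample_id", "marker")]))
    stop("duplicate (sample_id, marker) in IHC table")
  x
}

#' Read an RNA-Seq TPM table
#'
#' @param path TSV, first column gene ids, header sample ids, cells TPM.
#' @return numeric matrix (genes x samples), all values >= 0.
#' @export
readTpmTable <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "numeric"
  if (anyNA(mat) || any(mat < 0)) stop("TPM values must be >= 0")
  mat
}

# formats a numeric column deterministically for report output
formatReportColumn <- function(x, name, pctDigits = 1, ratioDigits = 4) {
  if (!is.numeric(x)) return(as.character(x))
  digits <- if (grepl("(_pct$|^PPA|^NPA|^PPV|^NPV|^OPA|percent)", name))
    pctDigits else ratioDigits
  out <- ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
  out
}

#' Write a deterministic tab-separated report
#'
#' Columns are written in their existing order; ratio-like numeric columns
#' are fixed to 4 decimals and percentage-like columns (names starting
#' with PPA/NPA/PPV/NPV/OPA or ending in `_pct`) to 1 decimal, so identical
#' inputs yield byte-identical files.
#'
#' @param results data.frame of results from any module.
#' @param path output path.
#' @param ratioDigits,pctDigits decimals for ratio-like and percentage-like
#'   columns (defaults 4 and 1).
#' @return the path, invisibly.
#' @export
writeReport <- function(results, path, ratioDigits = 4, pctDigits = 1) {
  stopifnot(is.data.frame(results))
  cols <- colnames(results)
  body <- if (nrow(results) == 0) character(0) else {
    cells <- lapply(cols, function(cn)
      formatReportColumn(results[[cn]], cn, pctDigits, ratioDigits))
    do.call(paste, c(cells, sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body), con)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes the count table (or one RCC file per sample), the panel
#' definition, the sample sheet and the ground-truth table, plus optional
#' paired IHC and TPM tables.
#'
#' @param sim output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param format `"table"` (default, one TSV) or `"rcc"` (one file per
#'   lane).
#' @param ihc,tpm optional outputs of [simulateIhc()] / [simulateRnaseq()].
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(sim, dir, format = c("table", "rcc"),
                        ihc = NULL, tpm = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pcs <- sim$counts
  paths <- c(panel = file.path(dir, "panel.tsv"),
             sheet = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  panel <- data.frame(gene = rownames(pcs),
                      code_class = codeClass(pcs),
                      nominal_conc = rowData(pcs)$NominalConc)
  write.table(panel, paths["panel"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sampleInfo(pcs), paths["sheet"], sep = "\t", quote = FALSE,
              row.names = FALSE,
              col.names = c("sample_id", "batch_id", "patient_id",
                            "tissue_site", "histology", "is_reference",
                            "tumor_pct"))
  truthTab <- data.frame(sample_id = names(sim$truth$subtype),
                         subtype = sim$truth$subtype,
                         lane_factor = sim$truth$lane_factor)
  write.table(truthTab, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (format == "table") {
    paths["counts"] <- file.path(dir, "counts.tsv")
    cnt <- data.frame(gene = rownames(pcs), panelCounts(pcs),
                      check.names = FALSE)
    write.table(cnt, paths["counts"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    acc <- paste0("SYN_", rownames(pcs))
    for (s in colnames(pcs)) {
      p <- file.path(dir, paste0(s, ".rcc"))
      writeRcc(data.frame(CodeClass = codeClass(pcs), Name = rownames(pcs),
                          Accession = acc, Count = panelCounts(pcs)[, s]),
               p, attributes = c(ID = s))
      paths[paste0("rcc_", s)] <- p
    }
  }
  if (!is.null(ihc)) {
    paths["ihc"] <- file.path(dir, "ihc.tsv")
    write.table(ihc, paths["ihc"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(tpm)) {
    paths["tpm"] <- file.path(dir, "tpm.tsv")
    write.table(data.frame(gene = rownames(tpm), tpm, check.names = FALSE),
                paths["tpm"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
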