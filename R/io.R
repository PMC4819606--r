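#' Read a cohort expression matrix and its sample metadata
#'
#' Reads a genes x samples table (genes as rows, a header row of sample ids,
#' gene ids in the first column) plus a two-column `sample_id,group` metadata
#' table, validates them against each other and returns an aligned
#' [CytokinePanel-class]. The delimiter is auto-detected from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' Missing cells in an RQ-scale matrix are treated as non-detects and read as
#' 0 (the count is reported via a message); missing cells on the Ct scale stay
#' `NA` (non-detected reactions). A sample present in the matrix but absent
#' from the metadata is an error, never silently dropped; metadata rows for
#' samples not in the matrix are ignored with a warning.
#'
#' @param matrixPath path to the expression CSV/TSV.
#' @param metadataPath path to the metadata CSV/TSV with columns
#'   `sample_id`, `group`.
#' @param valueScale `"rq"` (default) or `"ct"`.
#' @param referenceGene reference gene id, required when `valueScale = "ct"`.
#' @return a validated [CytokinePanel-class]
#' @seealso [writeResults()], [writeFixture()]
#' @export
readCohort <- function(matrixPath, metadataPath, valueScale = c("rq", "ct"),
                       referenceGene = NULL) {
  valueScale <- match.arg(valueScale)
  if (identical(valueScale, "ct") && is.null(referenceGene))
    stop("a Ct-scale table requires 'referenceGene'")
  raw <- utils::read.table(matrixPath, header = TRUE, sep = .delim(matrixPath),
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs a gene-id column and >=1 sample")
  geneIds <- raw[[1L]]
  if (anyDuplicated(geneIds))
    stop("duplicated gene id(s): ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicated sample id(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  values <- vapply(raw[-1L], function(col) {
    col[col == ""] <- NA_character_
    suppressWarnings(num <- as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop("non-numeric cell(s) in expression matrix, e.g. '", col[bad[1L]], "'")
    num
  }, numeric(length(geneIds)))
  values <- matrix(values, nrow = length(geneIds),
                   dimnames = list(geneIds, sampleIds))
  if (identical(valueScale, "rq") && anyNA(values)) {
    nmiss <- sum(is.na(values))
    message(nmiss, " missing RQ cell(s) treated as non-detects (0)")
    values[is.na(values)] <- 0
  }

  meta <- utils::read.table(metadataPath, header = TRUE,
                            sep = .delim(metadataPath), check.names = FALSE,
                            colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("metadata must have 'sample_id' and 'group' columns")
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample id(s) in metadata")
  absent <- setdiff(sampleIds, meta$sample_id)
  if (length(absent))
    stop("sample(s) in matrix but missing from metadata: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(meta$sample_id, sampleIds)
  if (length(extra)) {
    warning("metadata row(s) for sample(s) not in the matrix ignored: ",
            paste(extra, collapse = ", "))
    meta <- meta[meta$sample_id %in% sampleIds, , drop = FALSE]
  }
  if (any(!nzchar(meta$group)) || anyNA(meta$group))
    stop("empty group label in metadata")
  groups <- stats::setNames(meta$group, meta$sample_id)
  CytokinePanel(values, groups = groups, valueScale = valueScale,
                referenceGene = if (is.null(referenceGene)) NA_character_
                                else referenceGene)
}

.delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

# full-precision numeric formatting so CSV round-trips are exact
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, "")
  out
}

.writeTable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], .fmtNum)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
}

#' Write analysis result tables plus a reproducibility manifest
#'
#' Serializes any mix of pipeline results to CSV files with stable column
#' order, and writes `manifest.json` recording the run configuration, the
#' seed, the imputation constant and the package version, so every result
#' file is traceable to the run that produced it.
#'
#' Recognized elements of `results` (by class / name):
#' * `screen` (from [screenGenes()]) -> `univariate.csv` + `pairwise.csv`
#' * `ranking` (from [rankByGroupDifference()]) -> `ranking.csv`
#' * a [RelevanceProfile-class] -> `relevance.csv`, sorted by descending
#'   relevance
#' * a [RocResult-class] -> `roc_points.csv` (columns threshold, fpr, tpr)
#'   and `scores.csv`
#' * a [CytokinePanel-class] -> `matrix.csv` + `metadata.csv`
#' Named elements gain their name as a file prefix, so several objects of one
#' kind can coexist.
#'
#' @param results a (possibly named) list of result objects.
#' @param outDir output directory, created if needed; must be non-empty.
#' @param config list of run parameters recorded in the manifest.
#' @param seed the top-level seed recorded in the manifest.
#' @return invisibly, the character vector of files written
#' @export
writeResults <- function(results, outDir, config = list(), seed = NULL) {
  if (is.null(outDir) || !nzchar(outDir)) stop("'outDir' must be a non-empty path")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  if (!is.list(results) || inherits(results, c("RocResult", "RelevanceProfile")))
    results <- list(results)
  files <- character()
  nm <- names(results)
  for (i in seq_along(results)) {
    prefix <- if (!is.null(nm) && nzchar(nm[i])) paste0(nm[i], "_") else ""
    files <- c(files, .writeOneResult(results[[i]], outDir, prefix))
  }
  manifest <- list(
    package = "panelGMLVQ",
    version = as.character(utils::packageVersion("panelGMLVQ")),
    seed = seed,
    config = config,
    files = basename(files)
  )
  mpath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(files, mpath))
}

.writeOneResult <- function(x, outDir, prefix) {
  if (is(x, "RocResult")) {
    p1 <- file.path(outDir, paste0(prefix, "roc_points.csv"))
    .writeTable(x@points[, c("threshold", "fpr", "tpr")], p1)
    p2 <- file.path(outDir, paste0(prefix, "scores.csv"))
    .writeTable(data.frame(sample_id = names(x@scores), score = unname(x@scores),
                           label = x@labels, stringsAsFactors = FALSE), p2)
    return(c(p1, p2))
  }
  if (is(x, "RelevanceProfile")) {
    p <- file.path(outDir, paste0(prefix, "relevance.csv"))
    df <- as.data.frame(x)
    .writeTable(df[order(df$rank), c("gene_id", "relevance", "rank")], p)
    return(p)
  }
  if (is(x, "CytokinePanel")) {
    v <- exprValues(x)
    p1 <- file.path(outDir, paste0(prefix, "matrix.csv"))
    .writeTable(cbind(data.frame(gene_id = rownames(v), stringsAsFactors = FALSE),
                      as.data.frame(v, check.names = FALSE)), p1)
    p2 <- file.path(outDir, paste0(prefix, "metadata.csv"))
    .writeTable(data.frame(sample_id = colnames(v),
                           group = as.character(sampleGroups(x)),
                           stringsAsFactors = FALSE), p2)
    return(c(p1, p2))
  }
  if (is.list(x) && all(c("genes", "pairwise") %in% names(x))) {
    p1 <- file.path(outDir, paste0(prefix, "univariate.csv"))
    .writeTable(as.data.frame(x$genes), p1)
    p2 <- file.path(outDir, paste0(prefix, "pairwise.csv"))
    .writeTable(as.data.frame(x$pairwise), p2)
    return(c(p1, p2))
  }
  if (is.data.frame(x) && all(c("gene_id", "diff_score", "rank") %in% names(x))) {
    p <- file.path(outDir, paste0(prefix, "ranking.csv"))
    .writeTable(x, p)
    return(p)
  }
  stop("unrecognized result object of class ", paste(class(x), collapse = "/"))
}

#' @export
#' @describeIn RelevanceProfile-class coerce to a data.frame with columns
#'   `gene_id`, `relevance`, `rank`
#' @param x a `RelevanceProfile`
#' @param ... unused
as.data.frame.RelevanceProfile <- function(x, ...) {
  data.frame(gene_id = x@geneId, relevance = x@relevance, rank = x@rank,
             stringsAsFactors = FALSE)
}
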