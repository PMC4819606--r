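#' Construct a CytokinePanel
#'
#' @param values genes x samples numeric matrix with unique row and column
#'   names (gene and sample ids).
#' @param groups outcome group of every sample: a character or factor vector
#'   of length `ncol(values)`, or a named vector matched against the sample
#'   ids.
#' @param valueScale `"rq"` (default), `"ct"` or `"logrq"`; see
#'   [CytokinePanel-class].
#' @param referenceGene endogenous reference gene id; required for Ct-scale
#'   panels.
#' @param preprocessing optional provenance list (imputation constant,
#'   log base, standardization parameters).
#' @return a [CytokinePanel-class]
#' @examples
#' m <- matrix(2^rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' CytokinePanel(m, groups = rep(c("uninflamed", "early_ra"), each = 2))
#' @export
CytokinePanel <- function(values, groups, valueScale = "rq",
                          referenceGene = NA_character_,
                          preprocessing = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("no group assigned to sample(s): ", paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values))
    stop("'groups' must assign one group to each of the ", ncol(values),
         " samples")
  groups <- as.factor(as.character(groups))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(values), valueScale),
    colData = S4Vectors::DataFrame(group = groups, row.names = colnames(values))
  )
  md <- list(reference_gene = referenceGene, preprocessing = preprocessing)
  S4Vectors::metadata(se) <- md
  new("CytokinePanel", se, valueScale = valueScale)
}

#' @describeIn CytokinePanel measurement scale of the assay
#' @param x a `CytokinePanel`
#' @export
setMethod("valueScale", "CytokinePanel", function(x) x@valueScale)

#' @describeIn CytokinePanel per-sample outcome groups as a factor
#' @export
setMethod("sampleGroups", "CytokinePanel", function(x) {
  SummarizedExperiment::colData(x)$group
})

#' @describeIn CytokinePanel the genes x samples value matrix
#' @export
setMethod("exprValues", "CytokinePanel", function(x) {
  SummarizedExperiment::assay(x, 1L)
})

#' @describeIn CytokinePanel preprocessing provenance list
#' @export
setMethod("preprocessingRecord", "CytokinePanel", function(x) {
  pp <- S4Vectors::metadata(x)$preprocessing
  if (is.null(pp)) list() else pp
})

#' @export
setMethod("show", "CytokinePanel", function(object) {
  cat(sprintf("CytokinePanel: %d genes x %d samples [%s scale]\n",
              nrow(object), ncol(object), object@valueScale))
  tab <- table(sampleGroups(object))
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  pp <- preprocessingRecord(object)
  if (length(pp)) {
    keys <- intersect(c("imputation_constant", "log_base", "standardized"),
                      names(pp))
    if (length(keys))
      cat("preprocessing:",
          paste(sprintf("%s=%s", keys, vapply(pp[keys], format, "")),
                collapse = ", "), "\n")
  }
  invisible(NULL)
})

# internal: replace the single assay keeping everything else, update metadata
.updatePanel <- function(x, values, valueScale = x@valueScale,
                         preprocessing = NULL, dropGenes = NULL) {
  md <- S4Vectors::metadata(x)
  if (!is.null(preprocessing))
    md$preprocessing <- utils::modifyList(
      if (is.null(md$preprocessing)) list() else md$preprocessing,
      preprocessing)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(values), valueScale),
    colData = SummarizedExperiment::colData(x)
  )
  S4Vectors::metadata(se) <- md
  new("CytokinePanel", se, valueScale = valueScale)
}

# internal: two-group subset with dropped factor levels
.subsetGroups <- function(panel, groups) {
  g <- as.character(sampleGroups(panel))
  unknown <- setdiff(groups, unique(g))
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  keep <- g %in% groups
  out <- panel[, keep]
  SummarizedExperiment::colData(out)$group <- factor(g[keep], levels = groups)
  out
}
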