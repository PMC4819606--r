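#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @import methods
NULL

.VALUE_SCALES <- c("ct", "rq", "logrq")

#' Cytokine panel container
#'
#' A `CytokinePanel` holds a genes x samples matrix of qPCR panel
#' measurements together with per-sample outcome groups. It extends
#' [SummarizedExperiment::SummarizedExperiment]: genes are rows, samples are
#' columns, and the outcome group of every sample lives in `colData(x)$group`.
#' The single assay is interpreted according to `valueScale(x)`:
#'
#' * `"ct"` — raw threshold-cycle values (lower Ct, more transcript);
#'   `metadata(x)$reference_gene` must name the endogenous reference gene.
#' * `"rq"` — relative quantities `2^-dCt`, non-negative; exact zeros are
#'   non-detects below the assay detection limit.
#' * `"logrq"` — imputed, log-transformed (optionally standardized)
#'   expression; all values finite. The preprocessing provenance
#'   (imputation constant, log base, standardization parameters) is carried
#'   in `metadata(x)$preprocessing`.
#'
#' @slot valueScale character scalar, one of `"ct"`, `"rq"`, `"logrq"`.
#' @seealso [CytokinePanel()] the constructor, [computeRQ()], [imputeZeros()],
#'   [logTransform()], [standardizeFeatures()]
#' @export
setClass("CytokinePanel",
  contains = "SummarizedExperiment",
  representation(valueScale = "character")
)

setValidity("CytokinePanel", function(object) {
  msg <- character()
  if (length(object@valueScale) != 1L || !object@valueScale %in% .VALUE_SCALES)
    msg <- c(msg, sprintf("valueScale must be one of %s",
                          paste(.VALUE_SCALES, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    v <- SummarizedExperiment::assay(object, 1L)
    if (identical(object@valueScale, "rq")) {
      if (any(!is.finite(v)))
        msg <- c(msg, "RQ values must all be finite (missing cells are read as 0)")
      else if (any(v < 0))
        msg <- c(msg, "RQ values must be >= 0")
    }
    if (identical(object@valueScale, "logrq") && any(!is.finite(v)))
      msg <- c(msg, "log-scale values must all be finite (impute zeros before the log)")
    if (identical(object@valueScale, "ct")) {
      ref <- S4Vectors::metadata(object)$reference_gene
      if (is.null(ref) || is.na(ref))
        msg <- c(msg, "a Ct-scale panel requires metadata()$reference_gene")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Trained GMLVQ classifier
#'
#' Generalized matrix relevance LVQ model: labelled prototypes `w_k` and a
#' square matrix `Omega` defining the global discriminative metric
#' `d(x, w) = (x - w)' Lambda (x - w)` with `Lambda = Omega' Omega`,
#' trace-normalized to 1 so the diagonal of Lambda is a relevance profile
#' over features. When trained behind a PCA front-end (`featureSpace =
#' "pca"`) the loadings needed to rotate relevances back to gene space are
#' stored in `pcaLoadings`.
#'
#' @slot prototypes numeric matrix, one prototype per row, in the model's
#'   feature space.
#' @slot prototypeLabels character, class label of each prototype.
#' @slot omega square numeric matrix with `sum(omega^2) == 1`.
#' @slot featureSpace `"gene"` or `"pca"`.
#' @slot pcaLoadings genes x components loadings (0 x 0 when not used).
#' @slot pcaCenter per-gene centering used by the PCA projection.
#' @slot featureNames names of the input features (gene ids).
#' @slot trace GLVQ cost after every accepted epoch (empty until trained).
#' @slot diagnostics optional per-epoch `trLambda` / `minEigenLambda` records.
#' @slot hyperparameters learning rates, epochs, phi, mode, seed, ...
#' @slot preprocessing provenance copied from the training panel.
#' @seealso [trainGMLVQ()], [relevanceProfile()], [decisionScore()]
#' @export
setClass("GMLVQModel",
  representation(
    prototypes = "matrix",
    prototypeLabels = "character",
    omega = "matrix",
    featureSpace = "character",
    pcaLoadings = "matrix",
    pcaCenter = "numeric",
    featureNames = "character",
    trace = "numeric",
    diagnostics = "list",
    hyperparameters = "list",
    preprocessing = "list"
  )
)

setValidity("GMLVQModel", function(object) {
  msg <- character()
  d <- ncol(object@prototypes)
  if (nrow(object@prototypes) != length(object@prototypeLabels))
    msg <- c(msg, "one label per prototype required")
  if (nrow(object@omega) != d || ncol(object@omega) != d)
    msg <- c(msg, "omega must be square in the model's feature space")
  tr <- sum(object@omega^2)
  if (abs(tr - 1) > 1e-8)
    msg <- c(msg, sprintf("Tr(Lambda) = %.12f, must equal 1", tr))
  if (!object@featureSpace %in% c("gene", "pca"))
    msg <- c(msg, "featureSpace must be 'gene' or 'pca'")
  if (identical(object@featureSpace, "pca") &&
      ncol(object@pcaLoadings) != d)
    msg <- c(msg, "pcaLoadings must have one column per model feature")
  if (length(unique(object@prototypeLabels)) < 2L)
    msg <- c(msg, "at least two classes required")
  if (length(msg)) msg else TRUE
})

#' Per-gene relevance profile of a GMLVQ model
#'
#' Diagonal of the learned relevance matrix mapped to gene space and
#' normalized to sum to 1; genes ranked by descending relevance
#' (ties broken by gene id).
#'
#' @slot geneId character gene identifiers.
#' @slot relevance numeric, non-negative, sums to 1.
#' @slot rank integer permutation of `1..n`.
#' @seealso [relevanceProfile()], [topKFeatures()]
#' @export
setClass("RelevanceProfile",
  representation(geneId = "character", relevance = "numeric", rank = "integer")
)

setValidity("RelevanceProfile", function(object) {
  msg <- character()
  n <- length(object@geneId)
  if (length(object@relevance) != n || length(object@rank) != n)
    msg <- c(msg, "geneId, relevance and rank must have equal length")
  if (any(object@relevance < -1e-10))
    msg <- c(msg, "relevances must be non-negative")
  if (n > 0 && abs(sum(object@relevance) - 1) > 1e-8)
    msg <- c(msg, "relevances must sum to 1")
  if (n > 0 && !identical(sort(object@rank), seq_len(n)))
    msg <- c(msg, "ranks must be a permutation of 1..n")
  if (length(msg)) msg else TRUE
})

#' ROC curve and AUC for a two-class score vector
#'
#' Holds per-sample decision scores with true labels, the swept ROC points
#' (one step per distinct score, +/-Inf sentinels) and the trapezoidal AUC,
#' which equals the tie-adjusted Mann-Whitney concordance probability.
#'
#' @slot scores named numeric decision scores (larger = more positive).
#' @slot labels character true labels, parallel to `scores`.
#' @slot positiveLabel the class treated as positive.
#' @slot points data.frame with columns `threshold`, `fpr`, `tpr`.
#' @slot auc area under the curve, in `[0, 1]`.
#' @slot scheme free-text validation-scheme descriptor.
#' @slot nPos,nNeg class counts.
#' @seealso [rocCurve()], [aucScore()], [crossvalScores()]
#' @export
setClass("RocResult",
  representation(
    scores = "numeric",
    labels = "character",
    positiveLabel = "character",
    points = "data.frame",
    auc = "numeric",
    scheme = "character",
    nPos = "integer",
    nNeg = "integer"
  )
)

setValidity("RocResult", function(object) {
  msg <- character()
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must be parallel")
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  p <- object@points
  if (!all(c("threshold", "fpr", "tpr") %in% names(p)))
    msg <- c(msg, "points must have threshold, fpr, tpr columns")
  else {
    if (nrow(p) < 2L || p$fpr[1] != 0 || p$tpr[1] != 0 ||
        p$fpr[nrow(p)] != 1 || p$tpr[nrow(p)] != 1)
      msg <- c(msg, "ROC must start at (0,0) and end at (1,1)")
    if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
      msg <- c(msg, "ROC points must be monotone non-decreasing")
  }
  if (length(msg)) msg else TRUE
})
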