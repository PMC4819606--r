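# map input-space data (genes as columns) into the model's feature space
.asModelSpace <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (identical(model@featureSpace, "pca")) {
    if (ncol(x) != length(model@pcaCenter))
      stop("dimension mismatch: model expects ", length(model@pcaCenter),
           " input features, got ", ncol(x))
    sweep(x, 2L, model@pcaCenter) %*% model@pcaLoadings
  } else {
    if (ncol(x) != ncol(model@prototypes))
      stop("dimension mismatch: model expects ", ncol(model@prototypes),
           " features, got ", ncol(x))
    x
  }
}

#' Classify samples with a trained GMLVQ model
#'
#' Assigns each sample the label of its nearest prototype under the learned
#' metric. An exact distance tie between prototypes of different classes is
#' broken towards the lexicographically smaller label, with a warning.
#'
#' @param object a [GMLVQModel-class].
#' @param newdata samples x features matrix (or a single feature vector) in
#'   the model's input space.
#' @return character vector of predicted labels
#' @export
setMethod("predict", "GMLVQModel", function(object, newdata) {
  x <- .asModelSpace(object, newdata)
  d2 <- .protoDist2(x, object@prototypes, object@omega)
  ord <- order(object@prototypeLabels)  # lexicographic tie-break
  d2 <- d2[, ord, drop = FALSE]
  labs <- object@prototypeLabels[ord]
  best <- max.col(-d2, ties.method = "first")
  tie <- vapply(seq_len(nrow(d2)), function(i) {
    hit <- d2[i, ] == d2[i, best[i]]
    length(unique(labs[hit])) > 1L
  }, TRUE)
  if (any(tie))
    warning(sum(tie), " sample(s) exactly equidistant between classes; ",
            "tie broken to the lexicographically smaller label")
  labs[best]
})

#' Two-class decision score
#'
#' `s(x) = (d_neg - d_pos) / (d_neg + d_pos)` where `d_pos` (`d_neg`) is the
#' distance to the closest prototype of the positive (negative) class.
#' Bounded in `[-1, 1]`; positive iff the sample is classified as positive;
#' monotone in the relative plausibility of the positive class, hence a
#' thresholdable score for tracing a ROC curve.
#'
#' @param model a two-class [GMLVQModel-class].
#' @param newdata samples x features matrix or single feature vector.
#' @param positiveLabel the class scored as positive.
#' @return numeric vector of scores in `[-1, 1]`
#' @export
decisionScore <- function(model, newdata, positiveLabel) {
  stopifnot(is(model, "GMLVQModel"))
  classes <- unique(model@prototypeLabels)
  if (length(classes) != 2L)
    stop("decision scores are defined for two-class models (found ",
         length(classes), " classes)")
  if (!positiveLabel %in% classes)
    stop("positiveLabel '", positiveLabel, "' not among model classes")
  x <- .asModelSpace(model, newdata)
  d2 <- .protoDist2(x, model@prototypes, model@omega)
  pos <- model@prototypeLabels == positiveLabel
  dPos <- apply(d2[, pos, drop = FALSE], 1L, min)
  dNeg <- apply(d2[, !pos, drop = FALSE], 1L, min)
  denom <- dPos + dNeg
  ifelse(denom == 0, 0, (dNeg - dPos) / denom)
}

#' PCA front-end: fit and project
#'
#' Centers the data and projects onto the top `m` right singular directions
#' (via [stats::prcomp]); the loadings are column-orthonormal, so relevances
#' learned in component space can be rotated back to gene space as
#' `diag(V Lambda V')`.
#'
#' @param x samples x features numeric matrix.
#' @param m number of components, `<= min(n_samples - 1, n_features)`.
#' @return list with `loadings` (features x m), `projected` (samples x m),
#'   `center` and `sdev`
#' @export
pcaFitProject <- function(x, m) {
  x <- as.matrix(x)
  mMax <- min(nrow(x) - 1L, ncol(x))
  if (m < 1L || m > mMax)
    stop("m must be in 1..", mMax, " for ", nrow(x), " samples x ",
         ncol(x), " features")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(loadings = pc$rotation[, seq_len(m), drop = FALSE],
       projected = pc$x[, seq_len(m), drop = FALSE],
       center = pc$center, sdev = pc$sdev[seq_len(m)])
}

#' @describeIn relevanceProfile gene-space relevance of a trained model:
#'   `diag(Lambda)` for models trained on genes, `diag(V Lambda V')` for
#'   models trained behind a PCA front-end; normalized to sum to 1 and
#'   ranked descending (ties broken by gene id, with a warning)
#' @export
setMethod("relevanceProfile", "GMLVQModel", function(model, ...) {
  if (!length(model@trace))
    stop("model is untrained (empty training trace)")
  lambda <- crossprod(model@omega)
  rel <- if (identical(model@featureSpace, "pca")) {
    v <- model@pcaLoadings
    rowSums((v %*% lambda) * v)  # diag(V Lambda V')
  } else {
    diag(lambda)
  }
  rel <- pmax(rel, 0)
  rel <- rel / sum(rel)
  names(rel) <- model@featureNames
  if (anyDuplicated(rel))
    warning("tied relevances; ranking ties broken by gene id")
  ord <- order(-rel, names(rel))
  rank <- integer(length(rel)); rank[ord] <- seq_along(rel)
  new("RelevanceProfile", geneId = names(rel), relevance = unname(rel),
      rank = rank)
})

#' @export
setMethod("show", "RelevanceProfile", function(object) {
  cat(sprintf("RelevanceProfile over %d genes; top genes:\n",
              length(object@geneId)))
  df <- as.data.frame(object)
  print(utils::head(df[order(df$rank), ], 5L), row.names = FALSE)
  invisible(NULL)
})

#' Top-k most relevant genes
#'
#' The `k` genes with the largest relevance, in rank order (ties broken
#' lexicographically by gene id at profile construction).
#'
#' @param profile a [RelevanceProfile-class].
#' @param k number of genes, `1 <= k <= n`.
#' @return character vector of `k` gene ids
#' @export
topKFeatures <- function(profile, k) {
  stopifnot(is(profile, "RelevanceProfile"))
  n <- length(profile@geneId)
  if (k <= 0) stop("k must be positive")
  if (k > n) stop("k = ", k, " exceeds the ", n, " genes in the profile")
  profile@geneId[order(profile@rank)][seq_len(k)]
}
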