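#' Cross-validated decision scores
#'
#' Scores every sample of a two-group comparison with a GMLVQ model trained
#' without it. Under `scheme = "loo"` (leave-one-out, the default — suited
#' to cohorts of 9-17 samples per group) each sample is held out in turn;
#' under `scheme = "split"` stratified random splits of size `fraction` are
#' held out `reps` times and the held-out scores pooled with a fold id.
#'
#' When `refitPreprocessing = TRUE` (the default; requires an RQ-scale
#' panel) the imputation constant, log transform and standardization are
#' re-fit on each training fold and applied to the held-out samples, so no
#' information leaks from validation into training. With
#' `refitPreprocessing = FALSE` a `logrq`-scale panel is used as-is —
#' matching an analysis that preprocesses once on the full cohort.
#'
#' All randomness (fold assignment, prototype jitter) derives from `seed`;
#' a training fold missing one of the two classes is an error for LOO and a
#' skipped fold (with a warning) for repeated splits.
#'
#' @param panel a [CytokinePanel-class]; RQ scale when
#'   `refitPreprocessing = TRUE`, `logrq` scale otherwise.
#' @param groups the two group labels compared.
#' @param positiveLabel group scored as positive (default the first of
#'   `groups`).
#' @param scheme `"loo"` or `"split"`.
#' @param fraction held-out fraction per split (default 0.1).
#' @param reps number of repeated splits (default 100).
#' @param seed top-level seed.
#' @param refitPreprocessing re-fit imputation/log/standardization per fold.
#' @param logBase,standardize preprocessing options used per fold.
#' @param trainArgs list of extra arguments for [trainGMLVQ()] (epochs,
#'   learning rates, pcaComponents, ...).
#' @return data.frame with columns `sample_id`, `fold`, `score`, `label`
#' @seealso [rocCurve()], [aucScore()]
#' @export
crossvalScores <- function(panel, groups, positiveLabel = groups[1L],
                           scheme = c("loo", "split"), fraction = 0.1,
                           reps = 100L, seed = 1L,
                           refitPreprocessing = TRUE, logBase = 2,
                           standardize = TRUE, trainArgs = list()) {
  scheme <- match.arg(scheme)
  stopifnot(is(panel, "CytokinePanel"))
  if (length(groups) != 2L) stop("exactly two groups required")
  if (!positiveLabel %in% groups) stop("positiveLabel must be one of 'groups'")
  panel <- .subsetGroups(panel, groups)
  labels <- as.character(sampleGroups(panel))
  ids <- colnames(panel)
  n <- length(ids)
  expectScale <- if (refitPreprocessing) "rq" else "logrq"
  if (!identical(valueScale(panel), expectScale))
    stop("refitPreprocessing = ", refitPreprocessing, " requires a '",
         expectScale, "'-scale panel")

  folds <- if (identical(scheme, "loo")) {
    lapply(seq_len(n), function(i) i)
  } else {
    withr::with_seed(.deriveSeed(seed, 1L), {
      lapply(seq_len(reps), function(r) {
        unlist(lapply(groups, function(gr) {
          idx <- which(labels == gr)
          sample(idx, max(1L, round(fraction * length(idx))))
        }), use.names = FALSE)
      })
    })
  }

  out <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(labels[train])) < 2L) {
      msg <- paste0("fold ", f, ": a class is absent from the training fold")
      if (identical(scheme, "loo")) stop(msg)
      warning(msg, "; fold skipped")
      next
    }
    # LOO fold seeds derive from the held-out sample id, so scores do not
    # depend on the column order of the panel
    foldKey <- if (identical(scheme, "loo"))
      sum(utf8ToInt(ids[test])) else 100L + f
    sc <- .scoreFold(panel, train, test, positiveLabel, refitPreprocessing,
                     logBase, standardize, trainArgs,
                     seed = .deriveSeed(seed, foldKey))
    out[[f]] <- data.frame(sample_id = ids[test], fold = f, score = sc,
                           label = labels[test], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.scoreFold <- function(panel, train, test, positiveLabel, refit, logBase,
                       standardize, trainArgs, seed) {
  v <- exprValues(panel)
  labels <- as.character(sampleGroups(panel))
  if (refit) {
    trPanel <- panel[, train]
    trPanel <- logTransform(imputeZeros(trPanel), base = logBase)
    pp <- preprocessingRecord(trPanel)
    teRaw <- v[, test, drop = FALSE]
    teRaw[teRaw == 0] <- pp$imputation_constant
    teLog <- log(teRaw, base = logBase)
    if (standardize) {
      trPanel <- standardizeFeatures(trPanel)
      xTest <- t(applyStandardization(trPanel, teLog))
    } else {
      xTest <- t(teLog[rownames(trPanel), , drop = FALSE])
    }
    xTrain <- t(exprValues(trPanel))
  } else {
    xTrain <- t(v[, train, drop = FALSE])
    xTest <- t(v[, test, drop = FALSE])
  }
  model <- do.call(trainGMLVQ, c(list(x = xTrain, labels = labels[train],
                                      seed = seed), trainArgs))
  decisionScore(model, xTest, positiveLabel)
}

#' ROC curve from decision scores
#'
#' Sweeps the classification threshold over the distinct score values
#' (with a `+Inf` sentinel so the curve starts at (0, 0) and ends at
#' (1, 1)); a sample is called positive when `score >= threshold`, and tied
#' scores move the curve in a single step. The AUC is the trapezoidal area,
#' which equals the tie-adjusted Mann-Whitney concordance probability.
#'
#' @param scores numeric decision scores (larger = more positive); names,
#'   if present, become sample ids.
#' @param labels true class labels, parallel to `scores`.
#' @param positiveLabel the positive class; both classes must be present.
#' @param scheme free-text descriptor stored with the result.
#' @return a [RocResult-class]
#' @export
rocCurve <- function(scores, labels, positiveLabel, scheme = "resubstitution") {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must be parallel")
  isPos <- labels == positiveLabel
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present (positive '", positiveLabel, "': ",
         nPos, ", negative: ", nNeg, ")")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- isPos[o]
  lastOfBlock <- c(s[-length(s)] != s[-1L], TRUE)  # one step per distinct score
  tp <- cumsum(y)[lastOfBlock]
  fp <- cumsum(!y)[lastOfBlock]
  points <- data.frame(
    threshold = c(Inf, s[lastOfBlock]),
    fpr = c(0, fp / nNeg),
    tpr = c(0, tp / nPos)
  )
  auc <- sum(diff(points$fpr) * (points$tpr[-1L] + points$tpr[-nrow(points)]) / 2)
  if (is.null(names(scores)))
    names(scores) <- paste0("sample", seq_along(scores))
  new("RocResult", scores = scores, labels = labels,
      positiveLabel = positiveLabel, points = points, auc = auc,
      scheme = scheme, nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Area under the ROC curve
#'
#' Tie-adjusted Mann-Whitney AUC:
#' `(number of concordant positive/negative pairs + 0.5 x ties) / (nPos x nNeg)`,
#' computed via midranks. Identical (to floating-point accuracy) to the
#' trapezoidal area reported by [rocCurve()].
#'
#' @inheritParams rocCurve
#' @return scalar in `[0, 1]`
#' @export
aucScore <- function(scores, labels, positiveLabel) {
  labels <- as.character(labels)
  isPos <- labels == positiveLabel
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[isPos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' @export
setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult [%s]: AUC = %.4f (positive '%s': n=%d, negative: n=%d)\n",
              object@scheme, object@auc, object@positiveLabel,
              object@nPos, object@nNeg))
  invisible(NULL)
})

#' @rdname panelGMLVQ-generics
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @describeIn RocResult-class the area under the curve
#' @param x a `RocResult`
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

#' @describeIn RocResult-class coerce the ROC points to a data.frame
#' @param ... unused
#' @export
as.data.frame.RocResult <- function(x, ...) x@points
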