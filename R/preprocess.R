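#' Relative quantification of a Ct-scale panel
#'
#' Converts threshold-cycle values to relative quantities against an
#' endogenous reference gene: `dCt = Ct(target) - Ct(reference)` per sample
#' and `RQ = 2^-dCt`, so one reference-gene equivalent of transcript gives
#' RQ = 1 and weaker expression gives smaller RQ. A target reaction that is
#' missing or at/above `ctMax` cycles is a non-detect and is recorded as
#' RQ = 0. The reference gene row is removed from the output.
#'
#' The subtraction order is the standard dCt convention; `orientation =
#' "ref_minus_target"` flips it (equivalent to `RQ -> 1/RQ`) for data exported
#' with the opposite sign.
#'
#' @param panel a Ct-scale [CytokinePanel-class].
#' @param referenceGene reference gene id; defaults to
#'   `metadata(panel)$reference_gene`.
#' @param ctMax detection cutoff in cycles (default 40): `Ct >= ctMax` is a
#'   non-detect.
#' @param orientation `"target_minus_ref"` (default) or `"ref_minus_target"`.
#' @return an RQ-scale [CytokinePanel-class] without the reference gene row
#' @examples
#' ct <- matrix(c(20, 25, 20, 20), 2, 2,
#'              dimnames = list(c("GAPDH", "IL6"), c("S1", "S2")))
#' p <- CytokinePanel(ct, groups = c("a", "b"), valueScale = "ct",
#'                    referenceGene = "GAPDH")
#' exprValues(computeRQ(p))  # IL6: 2^-5, 1
#' @export
computeRQ <- function(panel, referenceGene = NULL, ctMax = 40,
                      orientation = c("target_minus_ref", "ref_minus_target")) {
  orientation <- match.arg(orientation)
  stopifnot(is(panel, "CytokinePanel"))
  if (!identical(valueScale(panel), "ct"))
    stop("computeRQ expects a Ct-scale panel")
  if (is.null(referenceGene))
    referenceGene <- S4Vectors::metadata(panel)$reference_gene
  ct <- exprValues(panel)
  if (is.null(referenceGene) || is.na(referenceGene) ||
      !referenceGene %in% rownames(ct))
    stop("reference gene '", referenceGene, "' not found in the panel")
  refCt <- ct[referenceGene, ]
  undet <- is.na(refCt) | refCt >= ctMax
  if (any(undet))
    stop("reference gene undetected in sample(s): ",
         paste(colnames(ct)[undet], collapse = ", "))
  ct <- ct[setdiff(rownames(ct), referenceGene), , drop = FALSE]
  dct <- sweep(ct, 2L, refCt, "-")
  if (identical(orientation, "ref_minus_target")) dct <- -dct
  rq <- 2^(-dct)
  nondet <- is.na(ct) | ct >= ctMax
  rq[nondet] <- 0
  .updatePanel(panel[setdiff(rownames(panel), referenceGene), ], rq,
               valueScale = "rq",
               preprocessing = list(reference_gene = referenceGene,
                                    ct_max = ctMax, orientation = orientation))
}

#' Impute non-detect zeros at the detection floor
#'
#' Replaces every exact zero in an RQ-scale matrix by a small positive
#' constant so the subsequent log transform is finite. Under the default
#' policy the constant is the smallest non-zero RQ of the whole matrix —
#' the observed detection floor of the dataset; it can be pinned with
#' `constant`. The constant used and the number of replaced cells are
#' recorded in the panel's preprocessing provenance.
#'
#' @param panel an RQ-scale [CytokinePanel-class] with at least one non-zero
#'   value.
#' @param constant optional positive override for the imputation constant.
#' @return the imputed panel (still RQ scale)
#' @export
imputeZeros <- function(panel, constant = NULL) {
  stopifnot(is(panel, "CytokinePanel"))
  if (!identical(valueScale(panel), "rq"))
    stop("imputeZeros expects an RQ-scale panel")
  v <- exprValues(panel)
  nz <- v[v > 0]
  if (!length(nz)) stop("all-zero matrix: no detection floor to impute from")
  const <- if (is.null(constant)) min(nz) else constant
  if (!is.numeric(const) || length(const) != 1L || const <= 0)
    stop("imputation constant must be a positive scalar")
  nzero <- sum(v == 0)
  v[v == 0] <- const
  .updatePanel(panel, v,
               preprocessing = list(imputation_constant = const,
                                    imputed_cells = nzero))
}

#' Log-transform an imputed RQ matrix
#'
#' Elementwise logarithm of the relative quantities. All values must be
#' strictly positive: run [imputeZeros()] first so non-detect zeros are at
#' the detection floor. Changing the base rescales every feature by one
#' positive constant and leaves rank-based statistics and (after
#' standardization) the classifier unchanged.
#'
#' @param panel an imputed RQ-scale [CytokinePanel-class].
#' @param base log base, > 1 (default 2, matching the `2^-dCt` scale).
#' @return a `logrq`-scale [CytokinePanel-class]
#' @export
logTransform <- function(panel, base = 2) {
  stopifnot(is(panel, "CytokinePanel"))
  if (!identical(valueScale(panel), "rq"))
    stop("logTransform expects an RQ-scale panel")
  if (!is.numeric(base) || base <= 1) stop("'base' must be > 1")
  v <- exprValues(panel)
  if (any(v <= 0))
    stop(sum(v <= 0), " non-positive value(s); run imputeZeros() before the log")
  .updatePanel(panel, log(v, base = base), valueScale = "logrq",
               preprocessing = list(log_base = base))
}

# population-SD standardization of a genes x samples matrix
.popSD <- function(m) sqrt(rowMeans((m - rowMeans(m))^2))

#' Standardize genes to zero mean, unit variance
#'
#' Per-gene z-scoring of a log-scale panel across samples (population SD),
#' making relevance values comparable across genes in the downstream metric
#' learner. Genes with zero variance carry no information for any
#' classifier and are dropped with a warning. The per-gene center and scale
#' are stored in the preprocessing record so held-out samples can be mapped
#' into the same space (see [applyStandardization()]).
#'
#' @param panel a `logrq`-scale [CytokinePanel-class] with >= 2 samples.
#' @return the standardized panel
#' @export
standardizeFeatures <- function(panel) {
  stopifnot(is(panel, "CytokinePanel"))
  if (!identical(valueScale(panel), "logrq"))
    stop("standardizeFeatures expects a log-scale panel")
  v <- exprValues(panel)
  if (ncol(v) < 2L) stop("need >= 2 samples to standardize")
  ctr <- rowMeans(v)
  sc <- .popSD(v)
  const <- sc == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped: ",
            paste(utils::head(rownames(v)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    v <- v[!const, , drop = FALSE]
    ctr <- ctr[!const]
    sc <- sc[!const]
    panel <- panel[!const, ]
  }
  z <- (v - ctr) / sc
  .updatePanel(panel, z,
               preprocessing = list(standardized = TRUE, center = ctr,
                                    scale = sc, dropped_constant = sum(const)))
}

#' Apply stored standardization parameters to new samples
#'
#' Maps held-out log-scale values into the feature space of a standardized
#' training panel using the training fold's per-gene center and scale —
#' the leakage-free way to preprocess validation samples.
#'
#' @param panel the standardized training [CytokinePanel-class] (source of
#'   the parameters), or a preprocessing record list with `center`/`scale`.
#' @param values genes x samples matrix of log-scale values for the new
#'   samples (rows matched by gene id).
#' @return the standardized matrix, rows restricted to the training genes
#' @export
applyStandardization <- function(panel, values) {
  pp <- if (is.list(panel)) panel else preprocessingRecord(panel)
  if (is.null(pp$center) || is.null(pp$scale))
    stop("no standardization parameters found; run standardizeFeatures() first")
  genes <- names(pp$center)
  missing <- setdiff(genes, rownames(values))
  if (length(missing))
    stop("new data lack gene(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  (values[genes, , drop = FALSE] - pp$center) / pp$scale
}

#' One-call preprocessing chain
#'
#' [computeRQ()] (when on the Ct scale), [imputeZeros()], [logTransform()]
#' and optionally [standardizeFeatures()], in the order the downstream
#' statistics expect.
#'
#' @param panel a [CytokinePanel-class] on the `ct` or `rq` scale.
#' @param referenceGene,ctMax,orientation passed to [computeRQ()] for
#'   Ct-scale input.
#' @param imputeConstant passed to [imputeZeros()].
#' @param logBase passed to [logTransform()].
#' @param standardize whether to z-score genes (default TRUE).
#' @return a `logrq`-scale [CytokinePanel-class]
#' @export
preprocessPanel <- function(panel, referenceGene = NULL, ctMax = 40,
                            orientation = "target_minus_ref",
                            imputeConstant = NULL, logBase = 2,
                            standardize = TRUE) {
  if (identical(valueScale(panel), "ct"))
    panel <- computeRQ(panel, referenceGene, ctMax, orientation)
  panel <- logTransform(imputeZeros(panel, imputeConstant), base = logBase)
  if (standardize) panel <- standardizeFeatures(panel)
  panel
}
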