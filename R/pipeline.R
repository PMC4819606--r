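#' End-to-end panel analysis pipeline
#'
#' Runs the full analysis chain on a cohort — preprocessing (impute zeros at
#' the detection floor, log-transform, standardize), per-gene
#' Kruskal-Wallis/Dunn screening, group-difference ranking, GMLVQ training
#' with relevance extraction for each requested two-class comparison, and
#' cross-validated ROC/AUC — and writes every result table plus a
#' reproducibility manifest to `outDir`. When no `panel` is supplied a
#' synthetic cohort is generated from `spec` (seeded from `seed`), making a
#' complete simulate -> preprocess -> univariate -> train -> evaluate run a
#' single call. Two runs with identical arguments produce byte-identical
#' output files.
#'
#' @param outDir output directory.
#' @param seed top-level seed; all stage seeds derive from it.
#' @param panel optional RQ-scale [CytokinePanel-class]; if `NULL`, a
#'   cohort is generated from `spec`.
#' @param spec a [syntheticCohortSpec()] used when `panel` is `NULL`
#'   (default: [studyDesignSpec()], the 117-gene four-group design with the
#'   chronic-inflammation and early-peak chemokine signatures planted).
#' @param rankGroups two groups ordering the univariate ranking table.
#' @param classifierPairs list of two-group comparisons; each trains a
#'   GMLVQ model (first element = positive class).
#' @param alpha,dunnAdjust,geneFdr passed to [screenGenes()].
#' @param logBase,standardize preprocessing options.
#' @param scheme,fraction,reps validation scheme (see [crossvalScores()]).
#' @param topK how many top-relevance genes to report per comparison.
#' @param trainArgs extra arguments for [trainGMLVQ()].
#' @return invisibly, a list with the preprocessed panel, screen, ranking,
#'   and per-comparison models, relevance profiles, resubstitution and
#'   cross-validated [RocResult-class]s and top-k gene lists
#' @export
runPipeline <- function(outDir, seed = 1L, panel = NULL,
    spec = studyDesignSpec(seed = .deriveSeed(seed, 0L)),
    rankGroups = c("resolving", "early_ra"),
    classifierPairs = list(c("established_ra", "uninflamed"),
                           c("early_ra", "resolving")),
    alpha = 0.05, dunnAdjust = "bonferroni", geneFdr = "none",
    logBase = 2, standardize = TRUE,
    scheme = "loo", fraction = 0.1, reps = 100L, topK = 10L,
    trainArgs = list()) {
  truth <- NULL
  if (is.null(panel)) {
    spec$seed <- .deriveSeed(seed, 0L)
    cohort <- generateCohort(spec)
    panel <- cohort$panel
    truth <- cohort$truth
  }
  if (!identical(valueScale(panel), "rq"))
    stop("runPipeline expects an RQ-scale cohort")
  logPanel <- preprocessPanel(panel, logBase = logBase,
                              standardize = standardize)
  screen <- screenGenes(logPanel, alpha = alpha, dunnAdjust = dunnAdjust,
                        geneFdr = geneFdr)
  ranking <- rankByGroupDifference(logPanel, rankGroups[1L], rankGroups[2L])

  comparisons <- list()
  results <- list(cohort = panel, screen = screen, ranking = ranking)
  for (k in seq_along(classifierPairs)) {
    pair <- classifierPairs[[k]]
    tag <- paste(pair, collapse = "_vs_")
    model <- do.call(trainGMLVQ,
                     c(list(x = logPanel, groups = pair,
                            seed = .deriveSeed(seed, 10L + k)), trainArgs))
    sub <- .subsetGroups(logPanel, pair)
    resub <- rocCurve(
      stats::setNames(decisionScore(model, t(exprValues(sub)), pair[1L]),
                      colnames(sub)),
      as.character(sampleGroups(sub)), pair[1L], scheme = "resubstitution")
    cv <- crossvalScores(panel, groups = pair, positiveLabel = pair[1L],
                         scheme = scheme, fraction = fraction, reps = reps,
                         seed = .deriveSeed(seed, 20L + k),
                         logBase = logBase, standardize = standardize,
                         trainArgs = trainArgs)
    cvRoc <- rocCurve(stats::setNames(cv$score, cv$sample_id), cv$label,
                      pair[1L], scheme = scheme)
    prof <- relevanceProfile(model)
    comparisons[[tag]] <- list(
      model = model, relevance = prof,
      topK = topKFeatures(prof, min(topK, length(prof@geneId))),
      resubstitution = resub, crossval = cvRoc)
    results[[paste0(tag, "_relevance")]] <- prof
    results[[paste0(tag, "_resub")]] <- resub
    results[[paste0(tag, "_cv")]] <- cvRoc
  }
  config <- list(
    alpha = alpha, dunn_adjustment = dunnAdjust, gene_fdr = geneFdr,
    log_base = logBase, standardize = standardize,
    imputation_constant = preprocessingRecord(logPanel)$imputation_constant,
    validation_scheme = scheme, split_fraction = fraction, reps = reps,
    top_k = topK, rank_groups = rankGroups,
    classifier_pairs = lapply(classifierPairs, paste, collapse = " vs "),
    train_args = trainArgs,
    n_significant_genes = screen$nSignificant,
    n_significant_kw_only = screen$nSignificantKW
  )
  writeResults(results, outDir, config = config, seed = seed)
  invisible(list(panel = logPanel, truth = truth, screen = screen,
                 ranking = ranking, comparisons = comparisons))
}
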