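#' Specification of a synthetic cytokine-panel cohort
#'
#' Describes a cohort generator emulating a low-density qPCR panel profiled
#' over patient outcome groups: per-gene log2-RQ baselines drawn once from
#' `Normal(baselineMean, baselineSD^2)`, additive group effects (in units of
#' the within-group SD) on a small planted gene set, within-group Gaussian
#' noise on the log2 scale, and a detection floor `delta` on the RQ scale
#' below which a measurement is recorded as exactly 0 (a non-detect). The
#' defaults mirror a 117-gene panel over four groups of sizes 10/9/17/12
#' with a detection floor of 2e-5.
#'
#' @param nGenes number of genes on the panel (default 117).
#' @param groupSizes named integer vector of samples per group; default
#'   `c(uninflamed = 10, resolving = 9, early_ra = 17, established_ra = 12)`.
#' @param informativeGenes named list: gene id -> named numeric vector of
#'   per-group effects in pooled-SD units (groups absent from the vector get
#'   effect 0).
#' @param baselineMean,baselineSD mean and SD of the per-gene log2-RQ
#'   baselines (defaults -8 and 3: most transcripts far below the reference
#'   gene, spanning several orders of magnitude).
#' @param withinSD within-group SD of log2-RQ (default 1.5).
#' @param delta detection floor on the RQ scale (default 2e-5).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   spec.
#' @param geneIds optional explicit gene ids (default `gene001`...).
#' @return an object of class `SyntheticCohortSpec`
#' @seealso [generateCohort()], [embedSignature()], [writeFixture()]
#' @export
syntheticCohortSpec <- function(nGenes = 117L,
    groupSizes = c(uninflamed = 10L, resolving = 9L, early_ra = 17L,
                   established_ra = 12L),
    informativeGenes = list(), baselineMean = -8, baselineSD = 3,
    withinSD = 1.5, delta = 2e-5, seed = 1L, geneIds = NULL) {
  if (nGenes < 1L) stop("nGenes must be >= 1")
  if (is.null(names(groupSizes)) || any(!nzchar(names(groupSizes))))
    stop("groupSizes must be a named vector")
  if (any(groupSizes < 2L)) stop("every group needs >= 2 samples")
  if (delta < 0) stop("delta must be >= 0")
  if (withinSD <= 0 || baselineSD < 0) stop("SDs must be positive")
  if (is.null(geneIds))
    geneIds <- sprintf("gene%03d", seq_len(nGenes))
  if (length(geneIds) != nGenes || anyDuplicated(geneIds))
    stop("geneIds must be ", nGenes, " unique ids")
  if (length(informativeGenes)) {
    if (is.null(names(informativeGenes)) ||
        anyDuplicated(names(informativeGenes)))
      stop("informativeGenes must be uniquely named by gene id")
    bad <- setdiff(names(informativeGenes), geneIds)
    if (length(bad))
      stop("informative gene(s) not on the panel: ", paste(bad, collapse = ", "))
    for (eff in informativeGenes) {
      if (is.null(names(eff)) || length(setdiff(names(eff), names(groupSizes))))
        stop("effects must be named by group")
    }
  }
  structure(list(nGenes = as.integer(nGenes), groupSizes = groupSizes,
                 informativeGenes = informativeGenes,
                 baselineMean = baselineMean, baselineSD = baselineSD,
                 withinSD = withinSD, delta = delta, seed = as.integer(seed),
                 geneIds = geneIds),
            class = "SyntheticCohortSpec")
}

#' Plant a gene signature into a cohort spec
#'
#' Returns a spec whose named genes carry a canonical effect pattern:
#'
#' * `"early_peak"` — expression peaks in early RA and is partially
#'   retained in established disease (effects, in within-SD units:
#'   early_ra 2.0, established_ra 0.8, resolving 0.5, uninflamed 0) —
#'   the transient early-disease chemokine pattern the pipeline is built
#'   to detect;
#' * `"two_group"` — a single elevated group (`effect` in `groups[1]`,
#'   0 elsewhere);
#' * `"null"` — all effects 0.
#'
#' The named genes are added to the panel's gene ids (replacing the last
#' unnamed genes) if not already present, keeping the panel size fixed.
#'
#' @param spec a [syntheticCohortSpec()].
#' @param genes gene ids carrying the signature (default two chemokine-like
#'   markers).
#' @param pattern `"early_peak"` (default), `"two_group"` or `"null"`.
#' @param effect overall effect scale multiplying the pattern (default 1
#'   for `"early_peak"`; the elevated-group effect for `"two_group"`).
#' @param group elevated group for `"two_group"` (default `"early_ra"`).
#' @return the modified spec
#' @export
embedSignature <- function(spec, genes = c("CXCL4like", "CXCL7like"),
                           pattern = c("early_peak", "two_group", "null"),
                           effect = NULL, group = "early_ra") {
  pattern <- match.arg(pattern)
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  if (!is.null(effect) && effect == 0 && !identical(pattern, "null"))
    return(spec)  # zero effect: nothing to plant
  groupNames <- names(spec$groupSizes)
  newGenes <- setdiff(genes, spec$geneIds)
  if (length(newGenes)) {
    # keep panel size: rename trailing null genes to the signature genes
    replaceable <- setdiff(spec$geneIds, c(names(spec$informativeGenes), genes))
    if (length(replaceable) < length(newGenes))
      stop("not enough free genes on the panel to add the signature")
    old <- utils::tail(replaceable, length(newGenes))
    spec$geneIds[match(old, spec$geneIds)] <- newGenes
  }
  eff <- switch(pattern,
    early_peak = {
      base <- c(early_ra = 2.0, established_ra = 0.8, resolving = 0.5,
                uninflamed = 0)
      missing <- setdiff(names(base), groupNames)
      if (length(missing))
        stop("pattern 'early_peak' needs group(s): ",
             paste(missing, collapse = ", "))
      base * (effect %||% 1)
    },
    two_group = {
      if (!group %in% groupNames) stop("unknown group: ", group)
      stats::setNames(effect %||% 2, group)
    },
    null = stats::setNames(numeric(length(groupNames)), groupNames)
  )
  for (g in genes) spec$informativeGenes[[g]] <- eff
  spec
}

#' Cohort spec emulating the profiled study design
#'
#' A 117-gene four-group cohort (uninflamed 10, resolving 9, early RA 17,
#' established RA 12) carrying the qualitative differential-expression
#' structure reported for synovial cytokine panels in early arthritis:
#'
#' * an 18-gene chronic-inflammation signature (`inflam01`..`inflam18`)
#'   elevated in established RA (2.0 within-SD) and early RA (1.5), with a
#'   mild transient response in resolving arthritis (0.3);
#' * a two-gene early-peak chemokine signature (`CXCL4like`, `CXCL7like`)
#'   highest in early RA (2.0), partially retained in established disease
#'   (0.8), mild in resolving arthritis (0.5);
#' * 97 null genes.
#'
#' The effect sizes are fixed design choices of the generator (see the
#' package vignette); the remaining parameters are the
#' [syntheticCohortSpec()] defaults.
#'
#' @param seed integer seed.
#' @return a `SyntheticCohortSpec`
#' @export
studyDesignSpec <- function(seed = 1L) {
  spec <- syntheticCohortSpec(seed = seed)
  spec <- embedSignature(spec)  # CXCL4like / CXCL7like early peak
  inflam <- sprintf("inflam%02d", 1:18)
  spec$geneIds[match(utils::tail(setdiff(
    spec$geneIds, c(names(spec$informativeGenes))), 18), spec$geneIds)] <- inflam
  for (g in inflam)
    spec$informativeGenes[[g]] <- c(established_ra = 2.0, early_ra = 1.5,
                                    resolving = 0.3, uninflamed = 0)
  spec
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [syntheticCohortSpec()]: per gene `g` a baseline
#' `b_g ~ Normal(baselineMean, baselineSD^2)`; for sample `i` in group `c`,
#' `log2RQ = b_g + effect[g, c] * withinSD + Normal(0, withinSD^2)`;
#' `RQ = 2^log2RQ`, and any RQ below `delta` is recorded as exactly 0
#' (a non-detect). Bit-identical under a fixed spec.
#'
#' @param spec a [syntheticCohortSpec()].
#' @return list with `panel` (an RQ-scale [CytokinePanel-class]) and
#'   `truth` (list: `trueMeans` gene x group matrix of mean log2-RQ,
#'   `informativeGenes`, `delta`, `spec`)
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  groups <- names(spec$groupSizes)
  nTotal <- sum(spec$groupSizes)
  groupOf <- rep(groups, spec$groupSizes)
  sampleIds <- sprintf("S%03d", seq_len(nTotal))
  effects <- matrix(0, spec$nGenes, length(groups),
                    dimnames = list(spec$geneIds, groups))
  for (g in names(spec$informativeGenes)) {
    eff <- spec$informativeGenes[[g]]
    effects[g, names(eff)] <- eff
  }
  withr::with_seed(spec$seed, {
    baseline <- stats::rnorm(spec$nGenes, spec$baselineMean, spec$baselineSD)
    noise <- matrix(stats::rnorm(spec$nGenes * nTotal, 0, spec$withinSD),
                    spec$nGenes, nTotal)
  })
  trueMeans <- baseline + effects * spec$withinSD
  log2rq <- trueMeans[, match(groupOf, groups), drop = FALSE] + noise
  rq <- 2^log2rq
  rq[rq < spec$delta] <- 0
  dimnames(rq) <- list(spec$geneIds, sampleIds)
  panel <- CytokinePanel(rq, groups = stats::setNames(groupOf, sampleIds),
                         valueScale = "rq")
  list(panel = panel,
       truth = list(trueMeans = trueMeans,
                    informativeGenes = names(spec$informativeGenes),
                    delta = spec$delta, spec = spec))
}

#' Write a synthetic cohort fixture to disk
#'
#' Generates the cohort and writes `matrix.csv` and `metadata.csv` in the
#' dialect read by [readCohort()], plus `truth.json` recording the planted
#' genes, their effects and the generator parameters.
#'
#' @param spec a [syntheticCohortSpec()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the generated cohort (as from [generateCohort()])
#' @export
writeFixture <- function(spec, outDir) {
  if (is.null(outDir) || !nzchar(outDir)) stop("'outDir' must be a non-empty path")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(spec)
  v <- exprValues(cohort$panel)
  .writeTable(cbind(data.frame(gene_id = rownames(v), stringsAsFactors = FALSE),
                    as.data.frame(v, check.names = FALSE)),
              file.path(outDir, "matrix.csv"))
  .writeTable(data.frame(sample_id = colnames(v),
                         group = as.character(sampleGroups(cohort$panel)),
                         stringsAsFactors = FALSE),
              file.path(outDir, "metadata.csv"))
  truth <- list(
    informative_genes = spec$informativeGenes,
    n_genes = spec$nGenes, group_sizes = as.list(spec$groupSizes),
    baseline_mean = spec$baselineMean, baseline_sd = spec$baselineSD,
    within_sd = spec$withinSD, delta = spec$delta, seed = spec$seed
  )
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}
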