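#' Kruskal-Wallis test over >= 2 groups
#'
#' Tie-corrected Kruskal-Wallis H on midranks with the chi-square
#' approximation (k - 1 df). When every pooled observation is identical the
#' statistic is defined as 0 (its tie-correction limit) and p = 1.
#'
#' @param valuesByGroup list of >= 2 non-empty numeric vectors.
#' @return list with elements `H` and `p`
#' @examples
#' kruskalWallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskalWallis <- function(valuesByGroup) {
  .checkGroups(valuesByGroup)
  x <- unlist(valuesByGroup, use.names = FALSE)
  g <- factor(rep(seq_along(valuesByGroup), lengths(valuesByGroup)))
  if (length(x) < 3L) stop("need a total of >= 3 observations")
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z tests on the pooled midranks following a
#' Kruskal-Wallis omnibus test. For groups i, j with mean ranks `Ri`, `Rj`
#' over the pooled sample of size N:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - sumT/(12(N-1))) (1/ni + 1/nj))`
#' with `sumT = sum(t^3 - t)` over tied value groups. Two-sided p values
#' come from the standard normal and are adjusted across the compared pairs.
#'
#' @param valuesByGroup named or unnamed list of >= 2 numeric vectors.
#' @param adjust multiplicity adjustment across pairs: `"bonferroni"`
#'   (default), `"holm"` or `"none"`.
#' @return data.frame with columns `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`
#' @examples
#' dunnPosthoc(list(a = 1:3, b = 4:6, c = 7:9))  # z(a,c) = -6/sqrt(5)
#' @export
dunnPosthoc <- function(valuesByGroup, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  .checkGroups(valuesByGroup)
  k <- length(valuesByGroup)
  nm <- names(valuesByGroup)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  x <- unlist(valuesByGroup, use.names = FALSE)
  n <- lengths(valuesByGroup)
  N <- length(x)
  r <- rank(x)  # midranks
  rbar <- vapply(split(r, rep(seq_len(k), n)), mean, 0)
  ties <- tabulate(match(x, unique(x)))  # tie-group sizes by exact value
  sumT <- sum(ties^3 - ties)
  varTerm <- N * (N + 1) / 12 - sumT / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  z <- p <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    se <- sqrt(varTerm * (1 / n[i] + 1 / n[j]))
    z[q] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  data.frame(
    group_a = nm[pairs[1L, ]], group_b = nm[pairs[2L, ]],
    z = z, p_raw = p,
    p_adjusted = stats::p.adjust(p, method = adjust),
    stringsAsFactors = FALSE
  )
}

.checkGroups <- function(valuesByGroup) {
  if (!is.list(valuesByGroup) || length(valuesByGroup) < 2L)
    stop("need a list of >= 2 groups")
  if (any(lengths(valuesByGroup) == 0L))
    stop("every group must contain >= 1 observation")
  if (any(!vapply(valuesByGroup, is.numeric, TRUE)))
    stop("groups must be numeric vectors")
}

#' Screen every gene for differential expression across groups
#'
#' Per-gene Kruskal-Wallis omnibus test followed by Dunn's pairwise
#' post-hoc comparisons. A gene is called significant when its omnibus p is
#' below `alpha` AND at least one adjusted pairwise p is below `alpha`. The
#' omnibus-only count is reported alongside. By default no correction is
#' applied across genes (each gene is screened on its own); set `geneFdr =
#' "bh"` for a Benjamini-Hochberg adjustment of the omnibus p values (the
#' significance call then uses the adjusted omnibus p).
#'
#' @param panel a `logrq`-scale [CytokinePanel-class] (any monotone scale
#'   works: the tests are rank-based).
#' @param alpha significance level (default 0.05).
#' @param dunnAdjust adjustment across pairwise comparisons within a gene.
#' @param geneFdr `"none"` (default) or `"bh"` across genes.
#' @return list with `genes` (data.frame: gene_id, H, p_kw, p_kw_across,
#'   n_significant_pairs, significant), `pairwise` (data.frame of all
#'   per-gene pairwise records), `nSignificant` (KW + Dunn criterion) and
#'   `nSignificantKW` (omnibus only)
#' @export
screenGenes <- function(panel, alpha = 0.05,
                        dunnAdjust = c("bonferroni", "holm", "none"),
                        geneFdr = c("none", "bh")) {
  dunnAdjust <- match.arg(dunnAdjust)
  geneFdr <- match.arg(geneFdr)
  stopifnot(is(panel, "CytokinePanel"))
  v <- exprValues(panel)
  g <- as.factor(as.character(sampleGroups(panel)))
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 samples")
  genes <- rownames(v)
  H <- pkw <- numeric(length(genes))
  npairs <- integer(length(genes))
  pwList <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    byGroup <- split(v[i, ], g)
    kw <- kruskalWallis(byGroup)
    H[i] <- kw$H; pkw[i] <- kw$p
    pw <- dunnPosthoc(byGroup, adjust = dunnAdjust)
    pw$significant <- pw$p_adjusted < alpha
    npairs[i] <- sum(pw$significant)
    pw <- cbind(gene_id = genes[i], pw, stringsAsFactors = FALSE)
    pwList[[i]] <- pw
  }
  pkwAcross <- if (identical(geneFdr, "bh")) stats::p.adjust(pkw, "BH") else pkw
  sig <- pkwAcross < alpha & npairs > 0L
  res <- data.frame(
    gene_id = genes, H = H, p_kw = pkw, p_kw_across = pkwAcross,
    n_significant_pairs = npairs, significant = sig,
    stringsAsFactors = FALSE
  )
  list(genes = res, pairwise = do.call(rbind, pwList),
       nSignificant = sum(sig), nSignificantKW = sum(pkwAcross < alpha))
}

#' Rank genes by between-group difference of mean expression
#'
#' Per gene, computes the mean log expression of every group, z-scores that
#' vector of group means across groups (the heat-map values), and ranks
#' genes by descending `mean(groupB) - mean(groupA)`. Ties are broken by
#' lexicographic gene id.
#'
#' @param panel a `logrq`-scale [CytokinePanel-class].
#' @param groupA,groupB the two groups whose mean difference orders the
#'   table (difference is B minus A).
#' @return data.frame with per-group mean columns (`mean_<group>`), z-scored
#'   mean columns (`z_<group>`), `diff_score` and `rank`
#' @export
rankByGroupDifference <- function(panel, groupA, groupB) {
  stopifnot(is(panel, "CytokinePanel"))
  g <- as.factor(as.character(sampleGroups(panel)))
  for (gr in c(groupA, groupB))
    if (!gr %in% levels(g)) stop("unknown group: ", gr)
  v <- exprValues(panel)
  means <- vapply(levels(g), function(l) rowMeans(v[, g == l, drop = FALSE]),
                  numeric(nrow(v)))
  means <- matrix(means, nrow = nrow(v),
                  dimnames = list(rownames(v), levels(g)))
  ctr <- rowMeans(means)
  sdv <- apply(means, 1L, stats::sd)
  zs <- (means - ctr) / ifelse(sdv == 0, 1, sdv)
  diff <- means[, groupB] - means[, groupA]
  ord <- order(-diff, rownames(v))
  rank <- integer(nrow(v)); rank[ord] <- seq_len(nrow(v))
  out <- data.frame(gene_id = rownames(v), stringsAsFactors = FALSE)
  for (l in levels(g)) out[[paste0("mean_", l)]] <- means[, l]
  for (l in levels(g)) out[[paste0("z_", l)]] <- zs[, l]
  out$diff_score <- diff
  out$rank <- rank
  out[order(out$rank), ]
}
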