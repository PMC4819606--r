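# Shared fixture builders and independent oracles.

# two-class Gaussian task: n1 + n2 samples, d features, class-2 mean shifted
# by `effect` SDs on the first `nInformative` features
makeGaussianTask <- function(n1 = 15, n2 = 15, d = 5, effect = 2,
                             nInformative = d, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm((n1 + n2) * d), n1 + n2, d)
    shift <- c(rep(effect, nInformative), rep(0, d - nInformative))
    x[(n1 + 1):(n1 + n2), ] <- sweep(
      x[(n1 + 1):(n1 + n2), , drop = FALSE], 2L, shift, "+")
    colnames(x) <- paste0("f", seq_len(d))
    list(x = x, labels = rep(c("a", "b"), c(n1, n2)))
  })
}

# small RQ panel with explicit values
makeRQPanel <- function(values, groups) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  CytokinePanel(values, groups = groups, valueScale = "rq")
}

# independent AUC oracle: explicit concordant/tied pair count
pairCountAUC <- function(scores, labels, positiveLabel) {
  pos <- scores[labels == positiveLabel]
  neg <- scores[labels != positiveLabel]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# independent per-sample-loop GLVQ cost oracle
loopCost <- function(model, x, labels) {
  lambda <- crossprod(model@omega)
  w <- model@prototypes
  pl <- model@prototypeLabels
  E <- 0
  for (i in seq_len(nrow(x))) {
    d <- vapply(seq_len(nrow(w)), function(k)
      squaredDistance(x[i, ], w[k, ], lambda), 0)
    dJ <- min(d[pl == labels[i]])
    dK <- min(d[pl != labels[i]])
    E <- E + (dJ - dK) / (dJ + dK)
  }
  E
}

# build a trained-looking two-class model directly from slots
manualModel <- function(prototypes, labels, omega,
                        featureNames = paste0("f", seq_len(ncol(prototypes)))) {
  new("GMLVQModel",
      prototypes = prototypes, prototypeLabels = labels, omega = omega,
      featureSpace = "gene", pcaLoadings = matrix(0, 0, 0),
      pcaCenter = numeric(), featureNames = featureNames,
      trace = c(0), diagnostics = list(),
      hyperparameters = list(phi = "identity", sigmoidGamma = 2),
      preprocessing = list())
}
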