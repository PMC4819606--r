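test_that("squaredDistance implements the relevance metric", {
  expect_equal(squaredDistance(c(1, 1), c(0, 0), diag(2) / 2), 1)
  expect_equal(squaredDistance(c(3, -2), c(3, -2), diag(2)), 0)
  # irrelevant direction contributes nothing
  expect_equal(squaredDistance(c(0, 5), c(0, 0), diag(c(1, 0))), 0)
  expect_error(squaredDistance(c(1, 2, 3), c(0, 0), diag(2)), "dimension")
})

test_that("muScore is the bounded GLVQ margin", {
  expect_equal(muScore(2, 2), 0)
  expect_equal(muScore(0, 1.5), -1)
  expect_equal(muScore(3, 1), 0.5)
  expect_warning(expect_equal(muScore(0, 0), 0), "degenerate")
  expect_error(muScore(-1, 2), "non-negative")
})

test_that("vectorized cost equals the per-sample loop oracle and obeys
           label-swap antisymmetry", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      x <- matrix(rnorm(8 * 3), 8, 3)
      labels <- rep(c("a", "b"), 4)
      o <- matrix(rnorm(9), 3, 3); o <- o / sqrt(sum(o^2))
      model <- manualModel(matrix(rnorm(6), 2, 3), c("a", "b"), o)
      expect_equal(glvqCost(model, x, labels), loopCost(model, x, labels),
                   tolerance = 1e-12)
      swapped <- manualModel(model@prototypes, c("b", "a"), o)
      expect_equal(glvqCost(swapped, x, labels),
                   -glvqCost(model, x, labels), tolerance = 1e-12)
    }
  })
  # every sample at its own prototype: mu = -1 each, E = -n
  w <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  model <- manualModel(w, c("a", "b"), diag(2) / sqrt(2))
  x <- w[c(1, 1, 2), ]
  expect_equal(glvqCost(model, x, c("a", "a", "b")), -3)
  expect_error(glvqCost(model, x, c("a", "a", "z")), "absent")
})

test_that("initGMLVQ starts at jittered class means with unit-trace metric", {
  task <- makeGaussianTask(seed = 3)
  m0 <- initGMLVQ(task$x, task$labels, jitterSD = 0)
  expect_equal(m0@prototypes[1, ], colMeans(task$x[task$labels == "a", ]),
               ignore_attr = TRUE)
  expect_equal(sum(m0@omega^2), 1, tolerance = 1e-12)
  expect_length(m0@trace, 0)
  m1 <- initGMLVQ(task$x, task$labels, seed = 7)
  m2 <- initGMLVQ(task$x, task$labels, seed = 7)
  expect_identical(m1@prototypes, m2@prototypes)
  expect_error(initGMLVQ(task$x, rep("a", nrow(task$x))), ">= 2 classes")
})

test_that("training drives a separable task to zero training error", {
  withr::with_seed(31, {
    x <- matrix(c(rnorm(20, -1, 0.1), rnorm(20, 1, 0.1)), ncol = 1)
    labels <- rep(c("lo", "hi"), each = 20)
  })
  for (s in c(1, 5, 9)) {
    m <- trainGMLVQ(x, labels, seed = s)
    expect_identical(sum(predict(m, x) != labels), 0L)
  }
})

test_that("zero learning rates leave the model unchanged", {
  task <- makeGaussianTask(seed = 4)
  init <- initGMLVQ(task$x, task$labels, seed = 2)
  m <- trainGMLVQ(task$x, task$labels, lrW = 0, lrOmega = 0, seed = 2)
  expect_equal(m@prototypes, init@prototypes, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(m@omega, init@omega, tolerance = 1e-14)
})

test_that("batch cost trace is non-increasing and the metric stays a
           trace-one PSD matrix", {
  for (s in 1:5) {
    task <- makeGaussianTask(n1 = 12, n2 = 10, d = 4, effect = 1, seed = s)
    m <- trainGMLVQ(task$x, task$labels, seed = s, diagnostics = TRUE)
    expect_true(all(diff(trainingTrace(m)) <= 1e-12))
    expect_true(all(abs(m@diagnostics$trLambda - 1) <= 1e-10))
    expect_true(all(m@diagnostics$minEigenLambda >= -1e-10))
  }
})

test_that("compiled and reference training engines agree", {
  task <- makeGaussianTask(n1 = 10, n2 = 10, d = 6, effect = 1.5, seed = 12)
  mc <- trainGMLVQ(task$x, task$labels, seed = 3, epochs = 80)
  mr <- trainGMLVQ(task$x, task$labels, seed = 3, epochs = 80, engine = "r")
  expect_equal(trainingTrace(mc), trainingTrace(mr), tolerance = 1e-8)
  expect_equal(mc@omega, mr@omega, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(predict(mc, task$x), predict(mr, task$x))
})

test_that("classification depends on Omega only through Lambda", {
  task <- makeGaussianTask(seed = 6)
  m <- trainGMLVQ(task$x, task$labels, seed = 1, epochs = 50)
  withr::with_seed(13, {
    r <- qr.Q(qr(matrix(rnorm(25), 5, 5)))  # random orthogonal
  })
  m2 <- m
  m2@omega <- r %*% m@omega
  expect_equal(crossprod(m2@omega), crossprod(m@omega), tolerance = 1e-12)
  expect_identical(predict(m2, task$x), predict(m, task$x))
  expect_equal(glvqCost(m2, task$x, task$labels),
               glvqCost(m, task$x, task$labels), tolerance = 1e-10)
})

test_that("exact ties are broken to the lexicographically smaller label", {
  model <- manualModel(matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE),
                       c("b", "a"), diag(2) / sqrt(2))
  expect_warning(lab <- predict(model, c(0, 0)), "tie")
  expect_identical(lab, "a")
  expect_identical(predict(model, matrix(c(-1, 0), 1)), "b")
})

test_that("decisionScore is the signed relative distance with antisymmetry", {
  model <- manualModel(matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE),
                       c("pos", "neg"), diag(2) / sqrt(2))
  expect_equal(decisionScore(model, c(0, 0), "pos"), 1)
  expect_equal(decisionScore(model, c(2, 0), "pos"), 0)
  withr::with_seed(14, x <- matrix(rnorm(10), 5, 2))
  expect_equal(decisionScore(model, x, "pos"),
               -decisionScore(model, x, "neg"), tolerance = 1e-12)
  three <- manualModel(matrix(rnorm(6), 3, 2), c("a", "b", "c"), diag(2) / sqrt(2))
  expect_error(decisionScore(three, c(0, 0), "a"), "two-class")
})

test_that("pcaFitProject yields orthonormal loadings matching the
           eigendecomposition oracle", {
  withr::with_seed(15, x <- matrix(rnorm(30 * 6), 30, 6))
  fit <- pcaFitProject(x, 4)
  expect_equal(crossprod(fit$loadings), diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  # projected variance per component = covariance eigenvalues
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(apply(fit$projected, 2, var), ev[1:4], tolerance = 1e-8, ignore_attr = TRUE)
  # full rank: exact reconstruction
  full <- pcaFitProject(x, 6)
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(full$projected %*% t(full$loadings), unclass(xc),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pcaFitProject(x, 7), "must be in 1..6")
})

test_that("relevanceProfile ranks the diagonal of Lambda and back-rotates
           through PCA loadings", {
  o <- diag(sqrt(c(0.5, 0.3, 0.2)))
  model <- manualModel(matrix(0, 2, 3) + c(0, 1), c("a", "b"), o,
                       featureNames = c("g1", "g2", "g3"))
  prof <- relevanceProfile(model)
  expect_equal(prof@relevance, c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_identical(topKFeatures(prof, 3), c("g1", "g2", "g3"))
  expect_equal(sum(prof@relevance), 1, tolerance = 1e-12)

  # identity "PCA" must reproduce the gene-space profile
  modelPCA <- model
  modelPCA@featureSpace <- "pca"
  modelPCA@pcaLoadings <- diag(3)
  modelPCA@pcaCenter <- rep(0, 3)
  expect_equal(relevanceProfile(modelPCA)@relevance, prof@relevance,
               tolerance = 1e-12)

  untrained <- model; untrained@trace <- numeric()
  expect_error(relevanceProfile(untrained), "untrained")
})

test_that("planted informative features dominate the learned relevances", {
  both <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    task <- makeGaussianTask(n1 = 14, n2 = 12, d = 10, effect = 3,
                             nInformative = 2, seed = 400 + s)
    m <- trainGMLVQ(task$x, task$labels, seed = s)
    top2 <- topKFeatures(relevanceProfile(m), 2)
    both <- both + sum(c("f1", "f2") %in% top2)
  }
  expect_gte(both / (2 * nSeeds), 0.95)
})

test_that("trained model matches an exhaustive grid-search cost minimizer in
           training accuracy", {
  # 2 features, 12 samples: feature 1 separates all but one planted overlap,
  # feature 2 is noise
  withr::with_seed(77, {
    x <- cbind(c(rnorm(6, -1, 0.15), rnorm(6, 1, 0.15)), rnorm(12, 0, 0.3))
    labels <- rep(c("a", "b"), each = 6)
    x[6, ] <- x[7, ]  # an 'a' sample coinciding with a class-b sample:
                      # no classifier can get both right, ceiling is 11/12
  })
  gridW <- seq(-1.5, 1.5, by = 0.25)
  gridL <- seq(0.05, 0.95, by = 0.15)
  best <- Inf; bestAcc <- NA
  for (w1 in gridW) for (w2 in gridW) for (l1 in gridL) {
    w <- matrix(c(w1, 0, w2, 0), 2, 2, byrow = TRUE)
    o <- diag(sqrt(c(l1, 1 - l1)))
    model <- manualModel(w, c("a", "b"), o)
    E <- glvqCost(model, x, labels)
    if (E < best) {
      best <- E
      # grid points with coincident prototypes tie everywhere; suppress the
      # tie-break warning for the oracle sweep
      bestAcc <- mean(suppressWarnings(predict(model, x)) == labels)
    }
  }
  m <- trainGMLVQ(x, labels, seed = 5)
  expect_equal(mean(predict(m, x) == labels), bestAcc)
})

test_that("online mode trains and records a per-epoch cost trace", {
  task <- makeGaussianTask(n1 = 10, n2 = 10, d = 3, effect = 3, seed = 18)
  m <- trainGMLVQ(task$x, task$labels, mode = "online", epochs = 40,
                  lrW = 0.05, lrOmega = 0.005, seed = 2)
  expect_length(trainingTrace(m), 41L)
  expect_lt(trainingTrace(m)[41], trainingTrace(m)[1])
  # per-sample updates are noisier than batch: allow a stray sample
  expect_gte(mean(predict(m, task$x) == task$labels), 0.95)
})

test_that("a PCA front-end trains in component space and reports gene-space
           relevances summing to one", {
  task <- makeGaussianTask(n1 = 12, n2 = 12, d = 8, effect = 2,
                           nInformative = 2, seed = 19)
  m <- trainGMLVQ(task$x, task$labels, pcaComponents = 5, seed = 1)
  expect_identical(m@featureSpace, "pca")
  expect_identical(ncol(m@prototypes), 5L)
  prof <- relevanceProfile(m)
  expect_length(prof@geneId, 8L)
  expect_equal(sum(prof@relevance), 1, tolerance = 1e-8)
  expect_true(all(prof@relevance >= -1e-10))
  # predictions accept gene-space input
  expect_length(predict(m, task$x), 24L)
})
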