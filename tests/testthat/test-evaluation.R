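test_that("rocCurve reproduces closed-form examples with valid geometry", {
  # perfect separation
  r1 <- rocCurve(c(0.9, 0.8, 0.4, 0.3), c("p", "p", "n", "n"), "p")
  expect_equal(auc(r1), 1)
  # 3 of 4 pairs concordant
  r2 <- rocCurve(c(0.9, 0.4, 0.8, 0.3), c("p", "p", "n", "n"), "p")
  expect_equal(auc(r2), 0.75)
  pts <- as.data.frame(r2)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(!is.unsorted(pts$fpr) && !is.unsorted(pts$tpr))
  # tied scores move the curve in a single step
  r3 <- rocCurve(c(0.5, 0.5, 0.5, 0.9), c("p", "n", "n", "p"), "p")
  expect_equal(nrow(as.data.frame(r3)), 3L)
  expect_error(rocCurve(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("trapezoidal AUC equals the concordant-pair oracle and rank formula", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      n <- sample(6:20, 1)
      scores <- round(rnorm(n), 1)  # rounding forces ties
      labels <- sample(c("p", "n"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      a1 <- auc(rocCurve(scores, labels, "p"))
      a2 <- aucScore(scores, labels, "p")
      a3 <- pairCountAUC(scores, labels, "p")
      expect_equal(a1, a3, tolerance = 1e-12)
      expect_equal(a2, a3, tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(24, {
    scores <- rnorm(40)
    labels <- rep(c("p", "n"), 20)
    ours <- aucScore(scores, labels, "p")
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("n", "p"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("AUC properties: ties, complement, monotone invariance", {
  labels <- c("p", "p", "n", "n", "n")
  expect_equal(aucScore(rep(1, 5), labels, "p"), 0.5)
  withr::with_seed(25, s <- rnorm(5))
  expect_equal(aucScore(s, labels, "p"), 1 - aucScore(s, labels, "n"),
               tolerance = 1e-12)
  expect_equal(aucScore(exp(s), labels, "p"), aucScore(s, labels, "p"),
               tolerance = 1e-12)
  expect_equal(auc(rocCurve(exp(s), labels, "p")),
               auc(rocCurve(s, labels, "p")), tolerance = 1e-12)
})

test_that("LOO cross-validation scores every sample exactly once", {
  spec <- syntheticCohortSpec(
    nGenes = 15, groupSizes = c(a = 6, b = 6), seed = 31,
    informativeGenes = list(gene001 = c(a = 3)))
  cohort <- generateCohort(spec)
  cv <- crossvalScores(cohort$panel, c("a", "b"), seed = 1,
                       trainArgs = list(epochs = 60))
  expect_identical(nrow(cv), 12L)
  expect_setequal(cv$sample_id, colnames(cohort$panel))
  # deterministic under a fixed seed
  cv2 <- crossvalScores(cohort$panel, c("a", "b"), seed = 1,
                        trainArgs = list(epochs = 60))
  expect_identical(cv, cv2)
})

test_that("LOO scores do not depend on the sample order of the panel", {
  spec <- syntheticCohortSpec(nGenes = 10, groupSizes = c(a = 5, b = 5),
                              seed = 32)
  cohort <- generateCohort(spec)
  cv <- crossvalScores(cohort$panel, c("a", "b"), seed = 2,
                       trainArgs = list(epochs = 50))
  perm <- withr::with_seed(1, sample(ncol(cohort$panel)))
  cvP <- crossvalScores(cohort$panel[, perm], c("a", "b"), seed = 2,
                        trainArgs = list(epochs = 50))
  m <- match(cv$sample_id, cvP$sample_id)
  expect_equal(cv$score, cvP$score[m], tolerance = 1e-6)
})

test_that("widely separated classes give correctly signed held-out scores", {
  spec <- syntheticCohortSpec(
    nGenes = 20, groupSizes = c(pos = 8, neg = 8), seed = 33,
    informativeGenes = stats::setNames(
      lapply(1:5, function(i) c(pos = 5)), sprintf("gene%03d", 1:5)))
  cohort <- generateCohort(spec)
  cv <- crossvalScores(cohort$panel, c("pos", "neg"), seed = 3)
  expect_true(all(cv$score[cv$label == "pos"] > 0))
  expect_true(all(cv$score[cv$label == "neg"] < 0))
})

test_that("repeated stratified splits pool held-out scores deterministically", {
  spec <- syntheticCohortSpec(nGenes = 10, groupSizes = c(a = 8, b = 8),
                              seed = 34)
  cohort <- generateCohort(spec)
  cv <- crossvalScores(cohort$panel, c("a", "b"), scheme = "split",
                       fraction = 0.25, reps = 10, seed = 4,
                       trainArgs = list(epochs = 40))
  expect_identical(sort(unique(cv$fold)), 1:10)
  expect_identical(nrow(cv), 40L)  # 2 + 2 held out per rep
  cv2 <- crossvalScores(cohort$panel, c("a", "b"), scheme = "split",
                        fraction = 0.25, reps = 10, seed = 4,
                        trainArgs = list(epochs = 40))
  expect_identical(cv, cv2)
})

test_that("LOO fails loudly when a class cannot appear in training", {
  withr::with_seed(36, v <- matrix(rexp(5 * 6), 5, 6))
  panel <- makeRQPanel(v, c("a", rep("b", 5)))  # a single 'a' sample
  expect_error(crossvalScores(panel, c("a", "b"), seed = 1,
                              trainArgs = list(epochs = 10)),
               "absent from the training fold")
})

test_that("topKFeatures returns the leading genes with contract checks", {
  prof <- new("RelevanceProfile", geneId = c("a", "b", "c"),
              relevance = c(0.5, 0.3, 0.2), rank = 1:3)
  expect_identical(topKFeatures(prof, 2), c("a", "b"))
  expect_identical(topKFeatures(prof, 3), c("a", "b", "c"))
  expect_error(topKFeatures(prof, 0), "positive")
  expect_error(topKFeatures(prof, 4), "exceeds")
})
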