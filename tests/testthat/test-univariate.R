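test_that("kruskalWallis reproduces hand-computed H and handles edge cases", {
  # three groups {1,2,3},{4,5,6},{7,8,9}: ranks are the values, group mean
  # ranks 2/5/8, grand mean 5, no ties:
  # H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  kw <- kruskalWallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE), tolerance = 1e-12)

  # all observations identical: tie-correction limit H = 0
  expect_equal(kruskalWallis(list(c(2, 2), c(2, 2, 2)))$H, 0)

  expect_error(kruskalWallis(list(1:3)), ">= 2 groups")
  expect_error(kruskalWallis(list(1:3, numeric())), ">= 1 observation")
})

test_that("two-group Kruskal-Wallis matches a rank-sum (Mann-Whitney) oracle", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      a <- round(rnorm(7), 3); b <- round(rnorm(9) + 0.5, 3)
      if (any(duplicated(c(a, b)))) next
      n <- length(a); m <- length(b); N <- n + m
      w <- sum(rank(c(a, b))[seq_len(n)]) - n * (n + 1) / 2  # MW U for group a
      z <- (w - n * m / 2) / sqrt(n * m * (N + 1) / 12)
      kw <- kruskalWallis(list(a, b))
      expect_equal(kw$H, z^2, tolerance = 1e-10)
      # chi-square(1) on z^2 is exactly the two-sided normal tail of z
      expect_equal(kw$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
    }
  })
})

test_that("kruskalWallis is invariant under strictly monotone transforms", {
  withr::with_seed(9, {
    groups <- list(rnorm(6), rnorm(5) + 1, rnorm(7))
    h0 <- kruskalWallis(groups)$H
    expect_equal(kruskalWallis(lapply(groups, exp))$H, h0, tolerance = 1e-12)
    expect_equal(kruskalWallis(lapply(groups, function(v) 3 * v - 10))$H, h0,
                 tolerance = 1e-12)
  })
})

test_that("dunnPosthoc reproduces hand-computed z and adjusts correctly", {
  # groups {1,2,3},{4,5,6},{7,8,9}: mean ranks 2, 8 for the outer pair;
  # variance term N(N+1)/12 = 7.5, z = -6 / sqrt(7.5 * (2/3)) = -6/sqrt(5)
  pw <- dunnPosthoc(list(g1 = 1:3, g2 = 4:6, g3 = 7:9))
  row13 <- pw[pw$group_a == "g1" & pw$group_b == "g3", ]
  expect_equal(row13$z, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(row13$p_raw, 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-12)
  # Bonferroni over the 3 pairs
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_raw), tolerance = 1e-12)
  expect_true(all(pw$p_adjusted >= pw$p_raw))

  # identical groups: z = 0, p = 1
  same <- dunnPosthoc(list(c(1, 2), c(1, 2), c(2, 1)))
  expect_equal(same$z, rep(0, 3))
  expect_equal(same$p_raw, rep(1, 3))

  expect_error(dunnPosthoc(list(1:3)), ">= 2 groups")
})

test_that("dunn z values are antisymmetric in the group pair", {
  withr::with_seed(10, {
    g <- list(a = rnorm(5), b = rnorm(6) + 1, c = rnorm(4) - 1)
    fwd <- dunnPosthoc(g)
    rev <- dunnPosthoc(rev(g))
    zf <- fwd[fwd$group_a == "a" & fwd$group_b == "c", "z"]
    zr <- rev[rev$group_a == "c" & rev$group_b == "a", "z"]
    expect_equal(zf, -zr, tolerance = 1e-12)
  })
})

test_that("dunn tie correction matches the explicit tie-sum formula", {
  g <- list(c(1, 2, 2, 3), c(2, 4, 4), c(5, 5, 6))
  x <- unlist(g)
  N <- length(x)
  ties <- table(x)
  sumT <- sum(ties^3 - ties)
  varTerm <- N * (N + 1) / 12 - sumT / (12 * (N - 1))
  r <- rank(x)
  rbar <- c(mean(r[1:4]), mean(r[5:7]), mean(r[8:10]))
  zExp <- (rbar[1] - rbar[2]) / sqrt(varTerm * (1 / 4 + 1 / 3))
  pw <- dunnPosthoc(g)
  expect_equal(pw$z[pw$group_a == "group1" & pw$group_b == "group2"], zExp,
               tolerance = 1e-12)
})

test_that("screenGenes recovers strongly planted genes and reports counts", {
  planted <- sprintf("gene%03d", 1:5)
  hits <- 0L
  nSeeds <- 10L
  for (s in seq_len(nSeeds)) {
    spec <- syntheticCohortSpec(nGenes = 40, seed = 100 + s)
    for (g in planted)
      spec$informativeGenes[[g]] <- c(early_ra = 3)
    cohort <- generateCohort(spec)
    lg <- preprocessPanel(cohort$panel, standardize = FALSE)
    sc <- screenGenes(lg, alpha = 0.05)
    hits <- hits + sum(planted %in%
                         sc$genes$gene_id[sc$genes$significant])
  }
  expect_gte(hits / (5 * nSeeds), 0.95)
})

test_that("screenGenes calls nothing on identical groups and respects the
           KW+Dunn double criterion", {
  v <- matrix(c(1, 2, 1, 2), nrow = 1)  # group a == group b
  v <- rbind(v, v)
  p <- makeRQPanel(v, c("a", "a", "b", "b"))
  lg <- logTransform(imputeZeros(p))
  sc <- screenGenes(lg)
  expect_identical(sc$nSignificant, 0L)
  expect_true(all(!sc$genes$significant))
  expect_identical(nrow(sc$pairwise), 2L)  # one pair per gene
})

test_that("rankByGroupDifference orders by mean difference with documented
           tie-break", {
  # gene means: resolving/early_ra = (1,3) beats (2,2.5)
  v <- 2^matrix(c(1, 1, 3, 3,
                  2, 2, 2.5, 2.5,
                  5, 5, 5, 5), 3, 4, byrow = TRUE,
                dimnames = list(c("gB", "gA", "gC"), paste0("s", 1:4)))
  p <- makeRQPanel(v, c("resolving", "resolving", "early_ra", "early_ra"))
  lg <- logTransform(imputeZeros(p))
  rk <- rankByGroupDifference(lg, "resolving", "early_ra")
  expect_identical(rk$gene_id[1:2], c("gB", "gA"))
  expect_equal(rk$diff_score[rk$gene_id == "gB"], 2)
  # z-scored group means are centered per gene
  zc <- rk$z_early_ra + rk$z_resolving
  expect_equal(zc, rep(0, 3), tolerance = 1e-12)
  # all-equal means: lexicographic gene order
  expect_identical(rk$gene_id[3], "gC")

  v2 <- v[, ]; rownames(v2) <- c("zz", "aa", "mm")
  v2[] <- 1
  p2 <- makeRQPanel(v2, c("resolving", "resolving", "early_ra", "early_ra"))
  rk2 <- rankByGroupDifference(logTransform(imputeZeros(p2)),
                               "resolving", "early_ra")
  expect_identical(rk2$gene_id, c("aa", "mm", "zz"))
  expect_error(rankByGroupDifference(lg, "resolving", "nope"), "unknown group")
})
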