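sym_runif <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(seq_len(n), seq_len(n))
  m
}

test_that("Mantel statistic is Spearman on triangles with exact anchors", {
  d1 <- sym_runif(15, 1)
  mt <- mantelTest(d1, d1, n_perm = 99, seed = 1)
  expect_equal(mt$rho, 1)
  expect_equal(mt$p, 1 / 100)
  # invariant under a monotone transform of the second matrix
  mt2 <- mantelTest(d1, d1^3, n_perm = 99, seed = 1)
  expect_equal(mt2$rho, 1)
  expect_error(mantelTest(d1, matrix(1, 15, 15) - diag(15)), "constant")
  # reproducible under a fixed seed
  d2 <- sym_runif(15, 2)
  expect_identical(mantelTest(d1, d2, n_perm = 199, seed = 5),
                   mantelTest(d1, d2, n_perm = 199, seed = 5))
})

test_that("Mantel agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  d1 <- sym_runif(18, 3); d2 <- sym_runif(18, 4)
  mine <- mantelTest(d1, d2, n_perm = 999, seed = 9)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman",
                       permutations = 999)
  expect_equal(mine$rho, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p - ref$signif), 0.05)
})

test_that("cophenetic correlation tracks block structure and has an LCA oracle", {
  cm <- block_community(n_groups = 4, n_per = 5, sp_per = 3)
  d <- pairwiseDissimilarity(cm, "BC")
  h <- buildHierarchy(d, cm, isopamParams(max_levels = 2))
  cc <- copheneticCorrelation(h, d)
  expect_gt(cc, 0.9)
  # oracle: dendrogram distance via explicit deepest-common-node search
  a <- assignments(h)
  n <- nrow(a); L <- ncol(a)
  dd_oracle <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { dd_oracle[i, j] <- 0; next }
    depth <- 0
    for (l in 1:L)
      if (a[i, l] == a[j, l])
        depth <- max(depth, lengths(strsplit(a[i, l], ".", fixed = TRUE)))
    dd_oracle[i, j] <- L + 1 - depth
  }
  dm <- distMatrix(d)
  lt <- lower.tri(dm)
  expect_equal(cc, cor(dm[lt], dd_oracle[lt]), tolerance = 1e-12)
  # invariant to a permutation of the samples
  ord <- sample(n)
  dm2 <- dm[ord, ord]
  h2 <- buildHierarchy(dm2, new("CommunityMatrix",
                                ba = baMatrix(cm)[ord, ],
                                sampleData = data.frame(
                                  row.names = rownames(dm2))),
                       isopamParams(max_levels = 2))
  expect_equal(copheneticCorrelation(h2, dm2), cc, tolerance = 1e-9)
})

test_that("adjusted Rand matches pair counting on all small partitions", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(5, 5, 7, 7)), 1)
  expect_equal(adjustedRand(1:6, rep(1, 6)), 0)
  parts <- set_partitions(5)
  for (p1 in parts) for (p2 in parts) {
    got <- adjustedRand(p1, p2)
    want <- ari_pairs(p1, p2)
    if (is.nan(want)) {
      # degenerate chance term: both metrics agree the pair is trivial
      expect_true(is.nan(got) || got == 1 || got == 0)
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("WSS follows the distance-based formula and Huygens' theorem", {
  d <- matrix(c(0, .5, .5, 0), 2, dimnames = list(1:2, 1:2))
  expect_equal(withinSS(d, c(1, 1)), 0.5^2 / 2)
  expect_equal(withinSS(d, c(1, 2)), 0)
  # Euclidean toy: distance-based WSS equals SS around centroids
  set.seed(6)
  pts <- matrix(rnorm(40), 20, 2)
  dm <- as.matrix(dist(pts))
  assign <- rep(1:4, each = 5)
  ss <- 0
  for (g in 1:4) {
    sub <- pts[assign == g, , drop = FALSE]
    ctr <- colMeans(sub)
    ss <- ss + sum(sweep(sub, 2, ctr)^2)
  }
  expect_equal(withinSS(dm, assign), ss, tolerance = 1e-9)
  # splitting a cluster cannot increase WSS
  assign2 <- assign; assign2[assign == 1][1:2] <- 5
  expect_lte(withinSS(dm, assign2), withinSS(dm, assign) + 1e-12)
})

test_that("cluster distance stats split within from between", {
  d <- matrix(c(0, .1, .9, .9,
                .1, 0, .9, .9,
                .9, .9, 0, .1,
                .9, .9, .1, 0), 4, dimnames = list(1:4, 1:4))
  st <- clusterDistanceStats(d, c(1, 1, 2, 2))
  expect_equal(unname(st$per_cluster), c(.1, .1))
  expect_equal(st$mean_within, .1)
  expect_equal(st$mean_between, .9)
  # pooled within mean equals the pair-weighted mean of per-cluster means
  set.seed(13)
  dm <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  asg <- c(rep(1, 7), rep(2, 5), rep(3, 3))
  st2 <- clusterDistanceStats(dm, asg)
  w <- choose(c(7, 5, 3), 2)
  expect_equal(st2$mean_within,
               sum(st2$per_cluster * w) / sum(w), tolerance = 1e-12)
  # single cluster: between undefined, singleton: within NA
  st3 <- clusterDistanceStats(d, rep(1, 4))
  expect_true(is.na(st3$mean_between))
  st4 <- clusterDistanceStats(d, c(1, 1, 1, 2))
  expect_true(is.na(st4$per_cluster["2"]))
})

test_that("Kruskal-Wallis H matches the closed form and rank invariance", {
  kw <- kruskalWallisGroups(c(1, 2, 3, 10, 11, 12), rep(1:2, each = 3))
  expect_equal(kw$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-9)
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1)
  kw2 <- kruskalWallisGroups(100 + 5 * c(1, 2, 3, 10, 11, 12),
                             rep(1:2, each = 3))
  expect_equal(kw2$H, kw$H)
  kw0 <- kruskalWallisGroups(rep(2, 8), rep(1:2, each = 4))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  expect_error(kruskalWallisGroups(1:4, rep(1, 4)), ">= 2 groups")
})

test_that("the evaluation report carries every comparison metric", {
  cm <- block_community(n_groups = 3, n_per = 5, sp_per = 3)
  set.seed(77)
  # sparse abundance noise: occasional out-of-block occurrences
  ba <- baMatrix(cm) +
    matrix(rbinom(15 * 9, 1, 0.1) * runif(15 * 9, 0.2, 2), 15, 9)
  cm <- new("CommunityMatrix", ba = ba,
            sampleData = data.frame(row.names = rownames(ba)))
  D <- matrix(runif(81, .2, 1), 9, 9); D <- (D + t(D)) / 2; diag(D) <- 0
  D <- D / max(D); dimnames(D) <- list(colnames(ba), colnames(ba))
  d_bc <- pairwiseDissimilarity(cm, "BC")
  d_da <- pairwiseDissimilarity(cm, "dA", sdist = D)
  prm <- isopamParams(max_levels = 2)
  h_bc <- buildHierarchy(d_bc, cm, prm)
  h_da <- buildHierarchy(d_da, cm, prm)
  elev <- setNames(rep(c(500, 1500, 2500), each = 5), rownames(ba))
  rep1 <- evaluateClustering(d_bc, d_da, h_bc, h_da, elevation = elev,
                             n_perm = 99, seed = 3)
  expect_named(rep1, c("level", "mantel", "adjusted_rand", "BC", "dA"))
  for (side in c("BC", "dA")) {
    expect_true(all(c("n_clusters", "cophenetic_corr", "wss",
                      "mean_within", "mean_between", "kruskal_wallis")
                    %in% names(rep1[[side]])))
    expect_gte(rep1[[side]]$wss, 0)
  }
  expect_lte(rep1$adjusted_rand, 1)
  rep2 <- evaluateClustering(d_bc, d_da, h_bc, h_da, elevation = elev,
                             n_perm = 99, seed = 3)
  expect_identical(rep1, rep2)
  f <- tempfile(fileext = ".json")
  writeReport(rep1, f)
  expect_true(jsonlite::validate(readLines(f, warn = FALSE) |>
                                   paste(collapse = "")))
})
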