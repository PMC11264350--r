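test_that("geodesic distances follow shortest paths on the kNN graph", {
  # 3 collinear points: the long direct pair is routed through the middle
  d3 <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3,
               dimnames = list(1:3, 1:3))
  geo <- geodesicDistances(d3, k = 1)
  expect_equal(geo["1", "3"], 2)
  expect_equal(geo["1", "2"], 1)
  # complete graph on a metric d returns d itself
  set.seed(14)
  pts <- matrix(rnorm(20), 10, 2)
  dm <- as.matrix(dist(pts))
  expect_equal(geodesicDistances(dm, k = 9), dm, tolerance = 1e-12)
  # geodesic >= direct dissimilarity entrywise for metric inputs
  geo5 <- geodesicDistances(dm, k = 3)
  expect_true(all(geo5 - dm >= -1e-12))
  expect_error(geodesicDistances(dm, k = 0), "k must")
  expect_error(geodesicDistances(dm[1:2, 1:2], k = 1), "3 samples")
})

test_that("disconnected neighbour graphs are bridged, keeping geodesics finite", {
  # two tight pairs far apart; k=1 keeps them disconnected before repair
  d <- matrix(c(0, .1, 5, 5,
                .1, 0, 5, 5,
                5, 5, 0, .1,
                5, 5, .1, 0), 4, dimnames = list(1:4, 1:4))
  geo <- geodesicDistances(d, k = 1)
  expect_true(all(is.finite(geo)))
  expect_equal(geo["1", "3"], 5)  # bridged by the minimum inter-component edge
})

test_that("classical-scaling embedding reproduces line geometry", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(1:3, 1:3))
  xy <- isomapEmbed(d, 1)
  expect_equal(as.matrix(dist(xy)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical samples embed at identical coordinates
  d4 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3)
  dimnames(d4) <- list(1:3, 1:3)
  xy4 <- isomapEmbed(d4, 1)
  expect_equal(unname(xy4[1, ]), unname(xy4[2, ]), tolerance = 1e-9)
  # stress is non-increasing in the number of axes
  set.seed(31)
  pts <- matrix(rnorm(60), 15, 4)
  dm <- as.matrix(dist(pts))
  stress <- vapply(1:4, function(a) {
    emb <- isomapEmbed(dm, a)
    sum((as.matrix(dist(emb)) - dm)^2)
  }, numeric(1))
  expect_true(all(diff(stress) <= 1e-9))
  expect_lt(stress[4], 1e-16)
})

test_that("PAM attains the exhaustive optimum on small instances", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(1:n, 1:n)
    fit <- pamCluster(dm, k)
    expect_equal(fit$objective, pam_exhaustive(dm, k), tolerance = 1e-12)
  }
})

test_that("PAM separates well-separated pairs and handles k = n", {
  d <- matrix(c(0, .1, 9, 9,
                .1, 0, 9, 9,
                9, 9, 0, .2,
                9, 9, .2, 0), 4, dimnames = list(1:4, 1:4))
  fit <- pamCluster(d, 2)
  expect_equal(fit$assignment, c(1, 1, 2, 2))
  expect_equal(fit$objective, 0.1 + 0.2, tolerance = 1e-12)
  fitn <- pamCluster(d, 4)
  expect_equal(fitn$objective, 0)
  expect_equal(fitn$medoids, 1:4)
})

test_that("PAM is deterministic and ties break to the lowest index", {
  # four identical points: medoids must be the lowest-index ones
  d <- matrix(1, 5, 5); diag(d) <- 0
  dimnames(d) <- list(1:5, 1:5)
  fit <- pamCluster(d, 2)
  expect_equal(fit$medoids, c(1, 2))
  dm <- as.matrix(dist(matrix(rnorm(30, sd = 2), 15, 2)))
  dimnames(dm) <- list(1:15, 1:15)
  expect_identical(pamCluster(dm, 3), pamCluster(dm, 3))
})

test_that("split quality counts faithful significant indicators", {
  cm <- block_community(n_groups = 2, n_per = 6, sp_per = 4)
  assign <- rep(1:2, each = 6)
  ba <- baMatrix(cm)
  q <- splitQuality(assign, ba, alpha = 0.05)
  expect_equal(q, 8)   # every species a perfect indicator, phi = 1
  # ubiquitous species contribute nothing
  ba2 <- cbind(ba, ubiquitous = 5)
  expect_equal(splitQuality(assign, ba2, alpha = 0.05), 8)
  # label permutation leaves the score unchanged
  expect_equal(splitQuality(3 - assign, ba, alpha = 0.05), q)
  expect_error(splitQuality(rep(1, 12), ba), ">= 2 clusters")
})

test_that("best split recovers constructed separability or declines", {
  cm <- block_community(n_groups = 2, n_per = 8, sp_per = 5, ba = 12)
  ba <- baMatrix(cm)
  d <- distMatrix(pairwiseDissimilarity(cm, "BC"))
  bs <- bestSplit(d, ba, isopamParams(min_cluster_size = 3))
  expect_false(is.null(bs))
  expect_equal(adjustedRand(bs$assignment, rep(1:2, each = 8)), 1)
  # a community with one ubiquitous species offers no indicator: no split
  one <- matrix(5 + runif(16 * 1, -1e-3, 1e-3), 16, 1,
                dimnames = list(rownames(ba), "only"))
  d1 <- as.matrix(dist(one)); d1 <- d1 / max(d1)
  expect_null(bestSplit(d1, one, isopamParams(min_cluster_size = 3)))
  # determinism
  bs2 <- bestSplit(d, ba, isopamParams(min_cluster_size = 3))
  expect_identical(bs, bs2)
})

test_that("hierarchies refine across levels and respect stop rules", {
  cm <- block_community(n_groups = 4, n_per = 6, sp_per = 4, ba = 10)
  d <- pairwiseDissimilarity(cm, "BC")
  h <- buildHierarchy(d, cm, isopamParams(max_levels = 3))
  a <- assignments(h)
  for (l in 1:2)
    expect_true(all(startsWith(a[, l + 1], a[, l])))
  expect_equal(adjustedRand(a[, 1], rep(1:4, each = 6)), 1)
  # cut() refines and terminal labels persist below their level
  for (l in 1:2) {
    c1 <- cutAssemblages(h, l); c2 <- cutAssemblages(h, l + 1)
    tab <- table(c1, c2)
    expect_true(all(colSums(tab > 0) == 1))
  }
  # max_levels = 1 gives a single partition
  h1 <- buildHierarchy(d, cm, isopamParams(max_levels = 1))
  expect_equal(ncol(assignments(h1)), 1L)
  # homogeneous data stays one leaf
  mono <- matrix(3, 10, 1, dimnames = list(sprintf("s%02d", 1:10), "sp"))
  cm0 <- new("CommunityMatrix", ba = mono,
             sampleData = data.frame(row.names = rownames(mono)))
  d0 <- matrix(0.5, 10, 10); diag(d0) <- 0
  dimnames(d0) <- list(rownames(mono), rownames(mono))
  h0 <- buildHierarchy(d0, cm0, isopamParams())
  expect_equal(unique(as.vector(assignments(h0))), "root")
  expect_equal(hierarchyNodes(h0)$stop_reason, "no_indicators")
})

test_that("hierarchy serialization produces the three artifacts", {
  cm <- block_community(n_groups = 2, n_per = 5, sp_per = 3)
  d <- pairwiseDissimilarity(cm, "BC")
  h <- buildHierarchy(d, cm, isopamParams(max_levels = 2))
  pre <- tempfile()
  nwk <- writeHierarchy(h, pre)
  expect_true(file.exists(paste0(pre, "_levels.tsv")))
  expect_true(file.exists(paste0(pre, "_nodes.json")))
  expect_true(file.exists(paste0(pre, "_dendrogram.nwk")))
  expect_match(nwk, "^\\(.*root:0;$")
  tsv <- read.delim(paste0(pre, "_levels.tsv"))
  expect_equal(nrow(tsv), 10L)
})

test_that("PAM never loses to the reference implementation and is locally optimal", {
  skip_if_not_installed("cluster")
  set.seed(55)
  # small instances take the exact enumeration path: objective can never
  # exceed the reference local search
  for (rep in 1:5) {
    dm <- as.matrix(dist(matrix(rnorm(50), 25, 2)))
    dimnames(dm) <- list(1:25, 1:25)
    fit <- pamCluster(dm, 2)
    ref <- cluster::pam(as.dist(dm), 2)
    ref_obj <- sum(apply(dm[, ref$id.med, drop = FALSE], 1, min))
    expect_lte(fit$objective, ref_obj + 1e-9)
  }
  # larger instances use BUILD+SWAP: verify a genuine swap-local optimum
  dm <- as.matrix(dist(matrix(rnorm(80), 40, 2)))
  dimnames(dm) <- list(1:40, 1:40)
  fit <- pamCluster(dm, 4)
  for (m in fit$medoids) for (h in setdiff(1:40, fit$medoids)) {
    M2 <- c(setdiff(fit$medoids, m), h)
    obj2 <- sum(apply(dm[, M2], 1, min))
    expect_gte(obj2, fit$objective - 1e-9)
  }
})
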