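# helper: a feature matrix with measure-like column names
featMatrix <- function(vals, measures = NULL) {
  if (is.null(measures)) measures <- paste0("f", seq_len(ncol(vals)))
  colnames(vals) <- measures
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
  cmFromMatrix(vals)
}

test_that("k-means recovers well-separated blobs exactly", {
  withr::with_seed(17, {
    blob <- rbind(matrix(rnorm(40 * 3, 0, 0.1), 40, 3),
                  matrix(rnorm(40 * 3, 8, 0.1), 40, 3))
  })
  rownames(blob) <- sprintf("g%03d", seq_len(80))
  cm <- featMatrix(blob)
  cl <- clusterNodes(cm, "kmeans", k = 2, seed = 0)
  truth <- stats::setNames(rep(1:2, each = 40), rownames(blob))
  lab <- labels(cl)[nodeIds(cm)]
  # partition identity up to label swap
  expect_equal(length(unique(paste(lab, truth[nodeIds(cm)]))), 2)
})

test_that("degenerate inputs follow the documented conventions", {
  same <- featMatrix(matrix(1, 10, 3))
  cl1 <- suppressWarnings(clusterNodes(same, "kmeans", k = 1))
  expect_equal(unname(unique(labels(cl1))), 1L)
  cl2 <- suppressWarnings(clusterNodes(same, "dbscan", eps = 0.5,
                                       minPts = 3))
  expect_equal(unname(unique(labels(cl2))), 1L)  # one cluster, no noise
  expect_warning(clusterNodes(same, "kmeans", k = 1), "single cluster")
})

test_that("density clustering separates blobs and flags far outliers", {
  withr::with_seed(23, {
    pts <- rbind(matrix(rnorm(30 * 2, 0, 0.2), 30, 2),
                 matrix(rnorm(30 * 2, 10, 0.2), 30, 2),
                 c(100, -100))  # far outlier, noise at any sane eps
  })
  cm <- featMatrix(pts)
  # features are z-scored inside clusterNodes; the outlier inflates the
  # column sd, so the blobs sit ~0.7 apart in z-space — eps must sit
  # between the within-blob spread (~0.02) and that separation
  cl <- clusterNodes(cm, "dbscan", eps = 0.3, minPts = 5)
  lab <- labels(cl)
  expect_equal(sort(unique(unname(lab))), c(-1L, 1L, 2L))
  expect_equal(sum(lab == -1L), 1)
})

test_that("permutation importance singles out the label-defining feature", {
  hits <- 0L
  nrep <- 8L
  for (s in seq_len(nrep)) {
    withr::with_seed(100 + s, {
      n <- 160
      degree <- runif(n)
      noise <- matrix(rnorm(n * 4), n, 4)
      vals <- cbind(degree, noise)
    })
    cm <- featMatrix(vals, c("degree", "betweenness", "closeness",
                             "eigenvector", "information"))
    lab <- as.integer(as.matrix(cm)[, "degree"] >
                        stats::median(as.matrix(cm)[, "degree"])) + 1L
    cl <- new("ClusterLabels",
              labels = stats::setNames(lab, nodeIds(cm)),
              method = "synthetic", params = list())
    rep <- permutationImportance(cm, cl, nTrees = 300, seed = s)
    if (names(which.max(importance(rep))) == "degree") hits <- hits + 1L
  }
  expect_gte(hits, nrep - 1L)
})

test_that("shuffling a constant column has exactly zero importance", {
  withr::with_seed(41, {
    vals <- cbind(runif(120), rnorm(120), 3.14)
  })
  cm <- featMatrix(vals, c("degree", "closeness", "constant"))
  lab <- as.integer(as.matrix(cm)[, "degree"] > 0.5) + 1L
  cl <- new("ClusterLabels", labels = stats::setNames(lab, nodeIds(cm)),
            method = "synthetic", params = list())
  rep <- permutationImportance(cm, cl, nTrees = 200, seed = 1)
  expect_identical(unname(importance(rep)["constant"]), 0)
})

test_that("labels unrelated to the features yield importances near zero", {
  withr::with_seed(55, {
    vals <- matrix(rnorm(150 * 4), 150, 4)
    lab <- sample(1:2, 150, replace = TRUE)
  })
  cm <- featMatrix(vals)
  cl <- new("ClusterLabels", labels = stats::setNames(lab, nodeIds(cm)),
            method = "synthetic", params = list())
  rep <- permutationImportance(cm, cl, nTrees = 300, seed = 2)
  # each importance within 2 sd of 0 (sd of the shuffle deltas, floored
  # by the test-set granularity)
  gran <- 1 / 45  # one test-set prediction
  tol <- pmax(2 * rep@importanceSd, 2 * gran)
  expect_true(all(abs(importance(rep)) <= tol))
})

test_that("permutation importance is reproducible and validated", {
  withr::with_seed(60, vals <- cbind(runif(80), rnorm(80)))
  cm <- featMatrix(vals, c("degree", "closeness"))
  lab <- as.integer(as.matrix(cm)[, "degree"] > 0.5) + 1L
  cl <- new("ClusterLabels", labels = stats::setNames(lab, nodeIds(cm)),
            method = "synthetic", params = list())
  r1 <- permutationImportance(cm, cl, nTrees = 100, seed = 7)
  r2 <- permutationImportance(cm, cl, nTrees = 100, seed = 7)
  expect_identical(importance(r1), importance(r2))

  one <- new("ClusterLabels",
             labels = stats::setNames(rep(1L, 80), nodeIds(cm)),
             method = "synthetic", params = list())
  expect_error(permutationImportance(cm, one, seed = 1), "single class")
})

test_that("noise points are excluded from the supervised analysis", {
  withr::with_seed(62, vals <- cbind(c(runif(60), 50), rnorm(61)))
  rownames(vals) <- sprintf("g%03d", seq_len(61))
  cm <- featMatrix(vals, c("degree", "closeness"))
  lab <- c(as.integer(vals[, 1][seq_len(60)] > 0.5) + 1L, -1L)
  cl <- new("ClusterLabels",
            labels = stats::setNames(lab, rownames(vals)),
            method = "dbscan", params = list())
  expect_s4_class(permutationImportance(cm, cl, nTrees = 100, seed = 3),
                  "ImportanceReport")
})

test_that("ternary coordinates normalize clipped importances", {
  mk <- function(v) new("ImportanceReport",
    importance = stats::setNames(v, c("closeness", "eigenvector",
                                      "information")),
    importanceSd = stats::setNames(rep(0, 3), c("closeness", "eigenvector",
                                                "information")),
    method = "kmeans", baselineAccuracy = 1, nTrees = 10L,
    nRepeats = 1L, seed = 0L)
  tc <- ternaryCoordinates(mk(c(0.2, 0.2, 0.2)))
  expect_equal(unlist(tc[1, 3:5], use.names = FALSE), rep(1/3, 3))
  tc2 <- ternaryCoordinates(mk(c(0.5, 0, 0)))
  expect_equal(unlist(tc2[1, 3:5], use.names = FALSE), c(1, 0, 0))
  tc3 <- ternaryCoordinates(mk(c(0.3, 0.1, 0.1)))
  expect_equal(unlist(tc3[1, 3:5], use.names = FALSE), c(0.6, 0.2, 0.2))
  # negative importances are clipped at zero before normalization
  tc4 <- ternaryCoordinates(mk(c(0.3, -0.2, 0.1)))
  expect_equal(unlist(tc4[1, 3:5], use.names = FALSE), c(0.75, 0, 0.25))
  expect_error(ternaryCoordinates(mk(c(-0.1, 0, -0.5))), "undefined")
  expect_error(ternaryCoordinates(mk(c(1, 1, 1)), measures = c("a", "b")),
               "exactly 3")
})

test_that("ternary output sums to 1 and is measure-permutation-equivariant", {
  withr::with_seed(70, v <- runif(3))
  imp <- stats::setNames(v, c("closeness", "eigenvector", "information"))
  mk <- function(imp) new("ImportanceReport", importance = imp,
    importanceSd = imp * 0, method = "dbscan", baselineAccuracy = 1,
    nTrees = 10L, nRepeats = 1L, seed = 0L)
  ms <- names(imp)
  t1 <- ternaryCoordinates(mk(imp), measures = ms)
  expect_equal(sum(unlist(t1[1, ms])), 1, tolerance = 1e-12)
  perm <- ms[c(3, 1, 2)]
  t2 <- ternaryCoordinates(mk(imp), measures = perm)
  expect_equal(unlist(t2[1, perm], use.names = FALSE),
               unlist(t1[1, perm], use.names = FALSE))
})

test_that("the assembled importance analysis runs on a planted network", {
  pn <- plantedNetwork(c(15, 30), 0.5, 0.05, 0.5, rngSeed = 13)
  cm <- computeCentralityMatrix(pn$network, pn$seeds)
  rep <- importanceAnalysis(cm, method = "kmeans", k = 3, nTrees = 150,
                            seed = 0)
  expect_s4_class(rep, "ImportanceReport")
  # the seed-dependent and duplicated columns never enter the analysis
  expect_false(any(c("personalized_pagerank", "eigenvector_dup") %in%
                     measureNames(rep)))
  expect_length(measureNames(rep), 7)
})
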