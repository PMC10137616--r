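## Which centralities carry the structure? Unsupervised node labels
## (DBSCAN / k-means on z-scored centrality features), random-forest
## permutation importance per centrality, and ternary coordinates for a
## chosen measure trio. DBSCAN is implemented here directly (the classic
## density-based procedure: core points by eps-neighbourhood size,
## clusters grown by density reachability).

#' Run an expression with a locally seeded RNG, restoring caller state
#' @noRd
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Per-column z-scoring (constant columns left at 0)
#' @noRd
zscoreColumns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  sweep(sweep(X, 2L, mu), 2L, sdv, "/")
}

#' Density-based clustering (DBSCAN)
#' @param X numeric matrix (rows = points)
#' @param eps neighbourhood radius
#' @param minPts core-point threshold (neighbourhood includes the point)
#' @return integer labels, -1 for noise, clusters numbered from 1
#' @noRd
dbscanLabels <- function(X, eps, minPts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  neighbours <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(neighbours) >= minPts
  labels <- rep(NA_integer_, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- setdiff(neighbours[[i]], i)
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (is.na(labels[j]) || labels[j] == -1L) {
        expand <- is.na(labels[j]) && core[j]
        labels[j] <- cluster
        if (expand)
          frontier <- union(frontier,
                            setdiff(neighbours[[j]],
                                    which(!is.na(labels) & labels > 0L)))
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' eps from the knee of the sorted k-NN distance curve
#'
#' Max-curvature heuristic: the point of the sorted k-th-NN distance
#' curve farthest (perpendicular) from the chord joining its endpoints.
#' @noRd
kneeEps <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  knn <- apply(D, 1L, function(row) sort(row)[k])
  y <- sort(knn)
  n <- length(y)
  if (n < 3L || y[n] == y[1L]) return(max(y[n], .Machine$double.eps))
  x <- seq_len(n)
  # perpendicular distance from the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1L]; dy <- y[n] - y[1L]
  dist <- abs(dy * x - dx * y + x[n] * y[1L] - y[n] * x[1L]) /
    sqrt(dx^2 + dy^2)
  eps <- y[which.max(dist)]
  max(eps, .Machine$double.eps)
}

#' Cluster nodes in centrality space
#'
#' Unsupervised node labels from the centrality features, used as the
#' classification target of the permutation-importance analysis.
#' Features are z-scored per column before clustering (density methods
#' are scale-degenerate on raw centralities). Deterministic given
#' \code{seed}.
#'
#' @param matrix A \code{\linkS4class{CentralityMatrix}} (typically after
#'   \code{\link{featureSubset}} has dropped seed-dependent columns).
#' @param method \code{"dbscan"} or \code{"kmeans"}.
#' @param k Number of k-means clusters.
#' @param eps DBSCAN radius; default is the knee of the sorted
#'   \code{minPts}-NN distance curve.
#' @param minPts DBSCAN core-point threshold.
#' @param seed RNG seed (k-means initialization).
#' @return A \code{\linkS4class{ClusterLabels}}; noise points are -1
#'   under \code{"dbscan"}.
#' @export
clusterNodes <- function(matrix, method = c("dbscan", "kmeans"), k = 4L,
                         eps = NULL, minPts = 5L, seed = 0L) {
  stopifnot(is(matrix, "CentralityMatrix"))
  method <- match.arg(method)
  X <- zscoreColumns(as.matrix(matrix))
  if (nrow(X) < 2L) stop("need at least 2 nodes to cluster")
  if (method == "kmeans") {
    k <- as.integer(k)
    if (k < 1L || k > nrow(X)) stop("k must be in 1..number of nodes")
    km <- withLocalSeed(seed,
      suppressWarnings(stats::kmeans(X, centers = k, nstart = 10L,
                                     iter.max = 100L)))
    labels <- as.integer(km$cluster)
    params <- list(k = k, seed = seed)
  } else {
    if (is.null(eps)) eps <- kneeEps(X, minPts)
    labels <- dbscanLabels(X, eps = eps, minPts = minPts)
    params <- list(eps = eps, minPts = minPts)
    if (all(labels == -1L))
      stop("DBSCAN labelled every node as noise; increase eps (used ",
           signif(eps, 4), ") or decrease minPts")
  }
  nClusters <- length(unique(labels[labels != -1L]))
  if (nClusters < 2L)
    warning("clustering produced a single cluster; labels cannot serve ",
            "as a classification target")
  new("ClusterLabels",
      labels = stats::setNames(labels, nodeIds(matrix)),
      method = method, params = params)
}

#' Permutation importance of each centrality for the cluster labels
#'
#' Trains a random-forest classifier (features: the centrality matrix;
#' target: the cluster labels; noise points excluded) on a stratified
#' 70/30 train/test split and measures, for each feature, the mean drop
#' in held-out accuracy over \code{nRepeats} random shuffles of that
#' feature's test-set column. A centrality whose shuffling noticeably
#' degrades accuracy is one the cluster structure depends on; shuffling a
#' constant column changes nothing, so its importance is exactly 0.
#' Bit-reproducible given \code{seed}.
#'
#' @param matrix A \code{\linkS4class{CentralityMatrix}}. Seed-dependent
#'   and duplicated columns (personalized PageRank, the eigenvector
#'   duplicate) should be removed first via \code{\link{featureSubset}};
#'   see \code{\link{importanceAnalysis}} for the assembled workflow.
#' @param labels A \code{\linkS4class{ClusterLabels}} over the same nodes
#'   with at least 2 non-noise classes.
#' @param nTrees Forest size.
#' @param nRepeats Shuffles per feature.
#' @param seed RNG seed (split, forest, shuffles).
#' @param trainFraction Fraction of non-noise nodes used for training.
#' @return An \code{\linkS4class{ImportanceReport}}.
#' @export
permutationImportance <- function(matrix, labels, nTrees = 500L,
                                  nRepeats = 10L, seed = 0L,
                                  trainFraction = 0.7) {
  stopifnot(is(matrix, "CentralityMatrix"), is(labels, "ClusterLabels"))
  if (!setequal(nodeIds(matrix), nodeIds(labels)))
    stop("matrix and labels cover different node sets")
  lab <- labels(labels)[nodeIds(matrix)]
  keep <- lab != -1L
  X <- as.matrix(matrix)[keep, , drop = FALSE]
  y <- factor(lab[keep])
  if (nlevels(y) < 2L)
    stop("labels have a single class; permutation importance undefined")
  res <- withLocalSeed(seed, {
    idxTrain <- unlist(lapply(levels(y), function(lv) {
      i <- which(y == lv)
      nTr <- max(1L, floor(trainFraction * length(i)))
      sample(i, nTr)
    }))
    idxTest <- setdiff(seq_along(y), idxTrain)
    if (length(idxTest) == 0L)
      stop("test split is empty; reduce trainFraction or supply more nodes")
    fit <- randomForest::randomForest(
      x = X[idxTrain, , drop = FALSE], y = y[idxTrain],
      ntree = as.integer(nTrees))
    Xte <- X[idxTest, , drop = FALSE]
    yte <- y[idxTest]
    acc <- function(M) mean(stats::predict(fit, M) == yte)
    base <- acc(Xte)
    drops <- vapply(seq_len(ncol(X)), function(j) {
      vapply(seq_len(nRepeats), function(r) {
        Xs <- Xte
        Xs[, j] <- Xs[sample(nrow(Xs)), j]
        base - acc(Xs)
      }, numeric(1))
    }, numeric(nRepeats))
    list(base = base,
         imp = colMeans(drops),
         sdv = apply(drops, 2L, stats::sd))
  })
  nms <- measureNames(matrix)
  new("ImportanceReport",
      importance = stats::setNames(res$imp, nms),
      importanceSd = stats::setNames(res$sdv, nms),
      method = labels@method,
      baselineAccuracy = res$base,
      nTrees = as.integer(nTrees), nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Clustering + permutation importance in one call
#'
#' The assembled centrality-importance analysis for one network: computes
#' (or takes) the centrality matrix, drops the seed-dependent
#' personalized PageRank and the duplicated eigenvector column, clusters
#' the nodes, and scores each remaining centrality by permutation
#' importance.
#'
#' @param matrix A \code{\linkS4class{CentralityMatrix}} with the default
#'   measure set.
#' @param method Clustering method, \code{"dbscan"} or \code{"kmeans"}.
#' @inheritParams clusterNodes
#' @inheritParams permutationImportance
#' @return An \code{\linkS4class{ImportanceReport}}.
#' @export
importanceAnalysis <- function(matrix, method = c("dbscan", "kmeans"),
                               k = 4L, eps = NULL, minPts = 5L,
                               nTrees = 500L, nRepeats = 10L, seed = 0L) {
  method <- match.arg(method)
  feat <- featureSubset(matrix,
    intersect(c("personalized_pagerank", "eigenvector_dup"),
              measureNames(matrix)))
  cl <- clusterNodes(feat, method = method, k = k, eps = eps,
                     minPts = minPts, seed = seed)
  permutationImportance(feat, cl, nTrees = nTrees, nRepeats = nRepeats,
                        seed = seed)
}

#' Ternary coordinates of three measures' importances
#'
#' Maps each report to a point in the 2-simplex spanned by three chosen
#' measures: importances are clipped at 0 and normalized to sum to 1, so
#' each report becomes one dot of a ternary plot. The conventional trio
#' is closeness, eigenvector and information centrality.
#'
#' @param reports A single \code{\linkS4class{ImportanceReport}} or a
#'   (optionally named) list of them.
#' @param measures Exactly 3 measure labels present in every report.
#' @return data.frame with columns \code{report}, \code{method}, and one
#'   coordinate column per measure; coordinate rows sum to 1.
#' @export
ternaryCoordinates <- function(reports,
                               measures = c("closeness", "eigenvector",
                                            "information")) {
  if (is(reports, "ImportanceReport")) reports <- list(reports)
  if (length(measures) != 3L) stop("exactly 3 measures required")
  nms <- names(reports)
  if (is.null(nms)) nms <- paste0("report", seq_along(reports))
  nms[nms == ""] <- paste0("report", which(nms == ""))
  rows <- lapply(seq_along(reports), function(i) {
    rep <- reports[[i]]
    stopifnot(is(rep, "ImportanceReport"))
    miss <- setdiff(measures, measureNames(rep))
    if (length(miss))
      stop("measure(s) absent from report '", nms[i], "': ",
           paste(miss, collapse = ", "))
    v <- pmax(importance(rep)[measures], 0)
    if (sum(v) == 0)
      stop("all three importances are <= 0 in report '", nms[i],
           "'; ternary point undefined")
    v <- v / sum(v)
    out <- data.frame(report = nms[i], method = rep@method,
                      stringsAsFactors = FALSE)
    out[measures] <- as.list(unname(v))
    out
  })
  do.call(rbind, rows)
}
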