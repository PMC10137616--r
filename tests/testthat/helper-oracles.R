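# Independent brute-force implementations used as oracles. Everything
# here works on dense base-R matrices and deliberately shares no code
# path with the package (no igraph): Floyd-Warshall distances, explicit
# shortest-path counting, dense eigen/linear solves, and explicit power
# iteration for the PageRank family.

# undirected graph from an adjacency matrix with node names
graphFromAdjacency <- function(A, ids = NULL) {
  n <- nrow(A)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  g
}

adjacencyOf <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A[order(rownames(A)), order(colnames(A))]
}

# all-pairs shortest path lengths, Floyd-Warshall
fwDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# number of shortest paths between every pair, by distance-layer DP
shortestPathCounts <- function(A, D) {
  n <- nrow(A)
  N <- matrix(0, n, n)
  diag(N) <- 1
  N[D == 1] <- 1
  maxd <- max(D[is.finite(D)])
  d <- 2
  while (d <= maxd) {
    P <- (N * (D == d - 1)) %*% A
    N[D == d] <- P[D == d]
    d <- d + 1
  }
  N
}

oracleDegree <- function(A) rowSums(A) / (nrow(A) - 1)

oracleBetweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  D <- fwDistances(A)
  N <- shortestPathCounts(A, D)
  b <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], "+") == D & N > 0
    through[v, ] <- FALSE; through[, v] <- FALSE
    diag(through) <- FALSE
    contrib <- outer(N[, v], N[v, ]) / ifelse(N > 0, N, 1)
    b[v] <- sum(contrib[through]) / 2  # each unordered pair counted twice
  }
  b * 2 / ((n - 1) * (n - 2))
}

oracleCloseness <- function(A) {
  n <- nrow(A)
  D <- fwDistances(A)
  vapply(seq_len(n), function(v) {
    dv <- D[v, ]
    reach <- is.finite(dv)
    r <- sum(reach)
    s <- sum(dv[reach])
    if (r <= 1 || s == 0) 0 else ((r - 1) / s) * ((r - 1) / (n - 1))
  }, numeric(1))
}

# principal eigenvector of the adjacency, unit L2, nonnegative (connected)
oracleEigenvector <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  abs(v)
}

# PageRank family by explicit dense power iteration (no dangling nodes
# assumed: connected graphs with n >= 2)
oraclePageRank <- function(A, damping = 0.85, teleport = NULL) {
  n <- nrow(A)
  if (is.null(teleport)) teleport <- rep(1 / n, n)
  M <- sweep(A, 2L, colSums(A), "/")
  p <- teleport
  for (i in 1:20000) {
    pn <- damping * as.numeric(M %*% p) + (1 - damping) * teleport
    if (sum(abs(pn - p)) < 1e-14) break
    p <- pn
  }
  pn
}

# current-flow closeness via eigen-decomposition pseudoinverse,
# per connected component
oracleInformation <- function(A) {
  n <- nrow(A)
  D <- fwDistances(A)
  out <- numeric(n)
  seen <- rep(FALSE, n)
  for (v in seq_len(n)) {
    if (seen[v]) next
    comp <- which(is.finite(D[v, ]))
    seen[comp] <- TRUE
    nc <- length(comp)
    if (nc < 2) next
    Ac <- A[comp, comp, drop = FALSE]
    L <- diag(rowSums(Ac)) - Ac
    e <- eigen(L, symmetric = TRUE)
    pos <- e$values > 1e-10
    Gamma <- e$vectors[, pos, drop = FALSE] %*%
      diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
    for (i in seq_len(nc)) {
      rsum <- sum(Gamma[i, i] + diag(Gamma) - 2 * Gamma[i, ])
      out[comp[i]] <- 1 / rsum
    }
  }
  out
}

oracleClustering <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)
  ifelse(k < 2, 0, tri / (k * (k - 1)))
}

# all nine default measures, in package column order, rows sorted by id
oracleCentralityMatrix <- function(A, seedIdx, damping = 0.85) {
  n <- nrow(A)
  tele <- rep(0, n); tele[seedIdx] <- 1 / length(seedIdx)
  ev <- oracleEigenvector(A)
  cbind(degree = oracleDegree(A),
        betweenness = oracleBetweenness(A),
        closeness = oracleCloseness(A),
        eigenvector = ev,
        pagerank = oraclePageRank(A, damping),
        personalized_pagerank = oraclePageRank(A, damping, tele),
        information = oracleInformation(A),
        eigenvector_dup = ev,
        clustering_coefficient = oracleClustering(A))
}

# RWR fixed point by dense linear solve: p = r (I - (1-r) M)^{-1} e
oracleRWR <- function(A, seedIdx, restart) {
  n <- nrow(A)
  M <- sweep(A, 2L, pmax(colSums(A), 1), "/")
  e <- rep(0, n); e[seedIdx] <- 1 / length(seedIdx)
  solve(diag(n) - (1 - restart) * M, restart * e)
}

# hypergeometric upper tail by explicit summation of the pmf
oracleHyperTail <- function(ks, K, N, k) {
  if (ks <= 0) return(1)
  xs <- ks:min(k, K)
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, k - xs)) / choose(N, k)
}

# full module-expansion trace by brute force; returns added ids in order
oracleDiamond <- function(A, ids, seedIds, nAdded) {
  inMod <- ids %in% seedIds
  added <- character(0)
  N <- length(ids)
  deg <- rowSums(A)
  for (step in seq_len(nAdded)) {
    cand <- which(!inMod)
    p <- vapply(cand, function(v)
      oracleHyperTail(sum(A[v, inMod]), sum(inMod), N, deg[v]), numeric(1))
    ksv <- vapply(cand, function(v) sum(A[v, inMod]), numeric(1))
    # same 12-significant-digit tie rule as the implementation
    ord <- order(signif(p, 12), -ksv,
                 match(ids[cand], sort(ids[cand], method = "radix")))
    pick <- cand[ord[1L]]
    added <- c(added, ids[pick])
    inMod[pick] <- TRUE
  }
  added
}

# --- graph generators -------------------------------------------------

isConnectedAdjacency <- function(A) {
  n <- nrow(A)
  reached <- c(TRUE, rep(FALSE, n - 1))
  repeat {
    new <- (A %*% reached) > 0 & !reached
    if (!any(new)) break
    reached <- reached | new
  }
  all(reached)
}

# every labelled connected graph on n nodes (n <= 5 is practical)
enumerateConnectedGraphs <- function(n) {
  m <- n * (n - 1) / 2
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    bits <- as.integer(intToBits(mask))[seq_len(m)]
    if (sum(bits) < n - 1) next  # cannot be connected
    A <- matrix(0, n, n)
    on <- pairs[bits == 1L, , drop = FALSE]
    A[on] <- 1
    A[on[, c(2, 1), drop = FALSE]] <- 1
    if (isConnectedAdjacency(A)) out[[length(out) + 1L]] <- A
  }
  out
}

# random connected G(n, p) adjacency (rejection sampling)
randomConnectedAdjacency <- function(n, p) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(runif(length(up)) < p)
    A <- A + t(A)
    if (isConnectedAdjacency(A)) return(A)
  }
}
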