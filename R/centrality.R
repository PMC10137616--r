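## The node feature space: nine centrality measures per node, assembled
## into a CentralityMatrix. Standard graph measures are delegated to
## igraph; eigenvector centrality is an explicit power iteration (unit L2
## norm, as in the reference network toolkits) and information centrality
## (current-flow closeness) is a dense per-component solve, since igraph
## provides neither in the exact variant used here.

#' Compute the centrality feature matrix of a network
#'
#' Encodes every node as a vector of centrality measures, the feature
#' space in which seed similarity is computed. Default measures, in fixed
#' column order (see \code{\link{centralityMeasures}}):
#' \describe{
#'   \item{degree}{\eqn{deg(v)/(n-1)}.}
#'   \item{betweenness}{Shortest-path betweenness, pair-normalized
#'     (\eqn{2/((n-1)(n-2))}).}
#'   \item{closeness}{Component-scaled closeness
#'     \eqn{(r-1)/\sum d \cdot (r-1)/(n-1)} with \eqn{r} the number of
#'     reachable nodes, so disconnected networks stay finite.}
#'   \item{eigenvector}{Principal adjacency eigenvector, unit L2 norm, by
#'     power iteration (tolerance 1e-6, max 1000 iterations); computed on
#'     the largest connected component with 0 elsewhere (with a warning)
#'     when the graph is disconnected.}
#'   \item{pagerank}{Damping 0.85, uniform teleport.}
#'   \item{personalized_pagerank}{Damping 0.85, teleport uniform over the
#'     seed members — the seeds act as the personalization vector.}
#'   \item{information}{Current-flow closeness (reciprocal total effective
#'     resistance), computed per connected component; 0 for singleton
#'     components.}
#'   \item{eigenvector_dup}{A duplicate of the eigenvector column, making
#'     the default vectors 9-dimensional; drop it with
#'     \code{dedupeEigenvector = TRUE} for an 8-dimensional space.}
#'   \item{clustering_coefficient}{Local clustering,
#'     triangles/\eqn{\binom{k}{2}}; 0 for degree < 2.}
#' }
#'
#' All measures are computed on the unweighted topology by default. With
#' \code{weighted = TRUE}, edge weights enter where a weighted variant is
#' standard: as distances for betweenness/closeness and as strengths for
#' degree, eigenvector and the PageRank pair; information centrality and
#' the clustering coefficient always use the unweighted topology.
#'
#' @param network \code{igraph} undirected simple graph with named
#'   vertices (see \code{\link{loadEdgeList}}).
#' @param seeds A \code{\linkS4class{SeedSet}} whose members are in the
#'   network; required for the personalized PageRank teleport.
#' @param weighted Logical; use the \code{weight} edge attribute.
#' @param dedupeEigenvector Logical; drop the duplicated eigenvector
#'   column, yielding 8 columns.
#' @param damping PageRank damping factor.
#' @param tol,maxIter Power-iteration controls for eigenvector centrality.
#' @return A \code{\linkS4class{CentralityMatrix}}, rows in lexicographic
#'   node order.
#' @export
#' @examples
#' g <- networkFixture("triangle")
#' m <- computeCentralityMatrix(g, seedSet("a"))
#' dim(m)  # 3 nodes x 9 measures
computeCentralityMatrix <- function(network, seeds, weighted = FALSE,
                                    dedupeEigenvector = FALSE,
                                    damping = 0.85, tol = 1e-6,
                                    maxIter = 1000L) {
  stopifnot(is(seeds, "SeedSet"))
  n <- igraph::vcount(network)
  if (n == 0L) stop("network has no nodes")
  ids <- igraph::V(network)$name
  if (is.null(ids)) stop("network vertices must be named")
  if (!all(members(seeds) %in% ids))
    stop("seed(s) not in network: ",
         paste(setdiff(members(seeds), ids), collapse = ", "))
  if (length(seeds) == 0L)
    stop("seed set is empty; personalized PageRank is undefined")

  useW <- weighted && "weight" %in% igraph::edge_attr_names(network)
  wDist <- if (useW) igraph::E(network)$weight else NA

  deg <- if (useW) igraph::strength(network) else igraph::degree(network)
  degree <- if (n > 1) deg / (n - 1) else rep(0, n)

  betweenness <- if (n > 2) {
    igraph::betweenness(network, weights = wDist, normalized = TRUE)
  } else rep(0, n)

  d <- igraph::distances(network, weights = wDist)
  closeness <- apply(d, 1L, function(row) {
    finite <- is.finite(row)
    r <- sum(finite)              # reachable nodes, self included
    s <- sum(row[finite])
    if (r <= 1L || s == 0) return(0)
    ((r - 1) / s) * ((r - 1) / (n - 1))
  })

  eigenvector <- eigenvectorPower(network, weighted = useW, tol = tol,
                                  maxIter = maxIter)

  pagerank <- igraph::page_rank(network, damping = damping,
                                weights = wDist)$vector
  pers <- as.numeric(ids %in% members(seeds))
  personalized <- igraph::page_rank(network, damping = damping,
                                    personalized = pers / sum(pers),
                                    weights = wDist)$vector

  information <- informationCentrality(network)

  clustering <- igraph::transitivity(network, type = "local",
                                     isolates = "zero")

  vals <- cbind(degree = degree, betweenness = betweenness,
                closeness = closeness, eigenvector = eigenvector,
                pagerank = pagerank, personalized_pagerank = personalized,
                information = information,
                eigenvector_dup = eigenvector,
                clustering_coefficient = clustering)
  rownames(vals) <- ids
  if (dedupeEigenvector)
    vals <- vals[, setdiff(colnames(vals), "eigenvector_dup"), drop = FALSE]
  vals <- vals[lexSort(ids), , drop = FALSE]
  if (!all(is.finite(vals))) {
    badm <- colnames(vals)[apply(!is.finite(vals), 2L, any)]
    stop("non-finite centrality values in measure(s): ",
         paste(badm, collapse = ", "))
  }
  new("CentralityMatrix", values = vals)
}

#' Principal-eigenvector centrality by power iteration
#'
#' Unit L2 norm, nonnegative orientation. Iterates on A + I so the
#' iteration also converges on bipartite components (same eigenvectors,
#' spectrum shifted off the symmetric +/- pair). On a disconnected graph
#' the centrality is defined on the largest connected component (ties
#' broken by smallest member identifier) and 0 elsewhere, with a warning.
#'
#' @noRd
eigenvectorPower <- function(network, weighted = FALSE, tol = 1e-6,
                             maxIter = 1000L) {
  ids <- igraph::V(network)$name
  n <- length(ids)
  comp <- igraph::components(network)
  out <- stats::setNames(rep(0, n), ids)
  if (comp$no > 1L) {
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
      firstMember <- vapply(cand, function(k)
        min(lexSort(ids[comp$membership == k])), "")
      cand <- cand[order(firstMember)][1L]
    }
    keep <- comp$membership == cand[1L]
    warning("network is disconnected; eigenvector centrality computed on ",
            "the largest connected component (", sum(keep), " of ", n,
            " nodes), 0 elsewhere")
    sub <- igraph::induced_subgraph(network, which(keep))
    out[igraph::V(sub)$name] <- eigenvectorPower(sub, weighted, tol, maxIter)
    return(out)
  }
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE,
    attr = if (weighted) "weight" else NULL)
  if (n == 1L) return(stats::setNames(1, ids))
  x <- rep(1 / sqrt(n), n)
  # stop when successive iterates agree to tol/100: the safety factor
  # keeps the *returned vector* within tol of the true eigenvector even
  # when the spectral gap slows the per-step contraction
  stopAt <- tol / 100
  for (i in seq_len(maxIter)) {
    xn <- as.numeric(A %*% x) + x   # (A + I) x
    nrm <- sqrt(sum(xn^2))
    if (nrm == 0) stop("eigenvector centrality: zero iterate")
    xn <- xn / nrm
    if (max(abs(xn - x)) < stopAt) {
      x <- xn
      names(x) <- ids
      return(abs(x) * sign(sum(x)) * sign(sum(x)))  # orient nonnegative
    }
    x <- xn
  }
  stop("eigenvector centrality power iteration did not converge in ",
       maxIter, " iterations")
}

#' Information (current-flow closeness) centrality
#'
#' For each connected component with Laplacian L and pseudoinverse
#' \eqn{\Gamma}, the effective resistance is
#' \eqn{R(s,t) = \Gamma_{ss} + \Gamma_{tt} - 2\Gamma_{st}} and the
#' centrality of s is \eqn{1 / \sum_t R(s,t)}. Singleton components get 0.
#' Always computed on the unweighted topology.
#'
#' @noRd
informationCentrality <- function(network) {
  ids <- igraph::V(network)$name
  out <- stats::setNames(rep(0, length(ids)), ids)
  comp <- igraph::components(network)
  for (k in seq_len(comp$no)) {
    memberIdx <- which(comp$membership == k)
    nc <- length(memberIdx)
    if (nc < 2L) next
    sub <- igraph::induced_subgraph(network, memberIdx)
    L <- as.matrix(igraph::laplacian_matrix(sub, weights = NA))
    # (L + J/nc)^{-1} = pinv(L) + J/nc  on the component
    Gamma <- solve(L + 1 / nc) - 1 / nc
    rsum <- nc * diag(Gamma) + sum(diag(Gamma)) - 2 * rowSums(Gamma)
    out[igraph::V(sub)$name] <- 1 / rsum
  }
  out
}

#' Restrict a CentralityMatrix to a subset of measures
#'
#' Drops the named measure columns, preserving the order of the rest.
#' Used, e.g., to exclude personalized PageRank (seed-dependent, so not a
#' node-intrinsic feature) and the duplicated eigenvector column before
#' the centrality-importance analysis.
#'
#' @param matrix A \code{\linkS4class{CentralityMatrix}}.
#' @param exclude Character vector of measure labels to drop (may be
#'   empty).
#' @return A \code{\linkS4class{CentralityMatrix}} with the remaining
#'   columns.
#' @export
featureSubset <- function(matrix, exclude = character()) {
  stopifnot(is(matrix, "CentralityMatrix"))
  have <- measureNames(matrix)
  unknown <- setdiff(exclude, have)
  if (length(unknown))
    stop("unknown measure label(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(have, exclude)
  if (length(keep) == 0L) stop("cannot exclude every measure")
  new("CentralityMatrix",
      values = matrix@values[, keep, drop = FALSE])
}
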