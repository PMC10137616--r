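## Comparator rankers: random walk with restart (network propagation) and
## iterative hypergeometric module expansion (the DIAMOnD scheme). Both
## emit RankingTable objects, so they plug directly into topKOverlap()
## and evaluateSeedRanks().

#' Random walk with restart
#'
#' Network-propagation ranking: a walker moves along edges with
#' probability \code{1 - restart} and teleports back to the seed set with
#' probability \code{restart}. Iterates
#' \deqn{p \leftarrow (1-r)\,M p + r\,e}
#' with \eqn{M} the column-stochastic transition matrix
#' (\eqn{M_{ij} = A_{ij}/deg(j)}) and \eqn{e} uniform over the seeds,
#' starting from \eqn{p_0 = e}, until the L1 change drops below
#' \code{tol}. Mass at degree-0 (dangling) nodes is redirected to the
#' restart vector, so the scores always form a probability distribution.
#' Nodes unreachable from every seed score 0.
#'
#' @param network \code{igraph} undirected simple graph with named
#'   vertices.
#' @param seeds A \code{\linkS4class{SeedSet}} present in the network.
#' @param restart Restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param maxIter Iteration cap.
#' @param weighted Logical; use the \code{weight} edge attribute in the
#'   transition matrix.
#' @return A \code{\linkS4class{RankingTable}} (method \code{"rwr"}),
#'   descending by stationary probability, lexicographic tie-break.
#' @export
#' @examples
#' g <- networkFixture("path3")
#' rwrRank(g, seedSet("a"), restart = 0.5)
rwrRank <- function(network, seeds, restart = 0.5, tol = 1e-10,
                    maxIter = 10000L, weighted = FALSE) {
  stopifnot(is(seeds, "SeedSet"))
  if (restart <= 0 || restart > 1)
    stop("restart probability must be in (0, 1]")
  ids <- igraph::V(network)$name
  if (!all(members(seeds) %in% ids))
    stop("seed(s) not in network: ",
         paste(setdiff(members(seeds), ids), collapse = ", "))
  useW <- weighted && "weight" %in% igraph::edge_attr_names(network)
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE,
    attr = if (useW) "weight" else NULL)
  colsum <- Matrix::colSums(A)
  dangling <- colsum == 0
  invdeg <- ifelse(dangling, 0, 1 / colsum)
  e <- stats::setNames(as.numeric(ids %in% members(seeds)), ids)
  e <- e / sum(e)
  p <- e
  residual <- Inf
  for (i in seq_len(maxIter)) {
    walk <- as.numeric(A %*% (p * invdeg))
    walk <- walk + sum(p[dangling]) * e  # dangling mass restarts
    pn <- (1 - restart) * walk + restart * e
    residual <- sum(abs(pn - p))
    p <- pn
    if (residual < tol) {
      names(p) <- ids
      return(rankNodes(p, seeds, method = "rwr"))
    }
  }
  stop("random walk did not converge within ", maxIter,
       " iterations (residual ", format(residual), ")")
}

#' Hypergeometric tail P(X >= ks)
#' @noRd
hyperTail <- function(ks, nModule, nPop, kDraws) {
  stats::phyper(ks - 1, nModule, nPop - nModule, kDraws,
                lower.tail = FALSE)
}

#' Iterative hypergeometric module expansion (DIAMOnD scheme)
#'
#' Grows a module outward from the seed set. At each step, every
#' non-module node with degree \eqn{k} and \eqn{k_s} links into the
#' current module (initially the seeds, size \eqn{s_0}) is scored by the
#' hypergeometric tail p-value \eqn{P(X \ge k_s)} with population
#' \eqn{N} (all network nodes), \eqn{s_0} successes and \eqn{k} draws;
#' the lowest-p node joins the module (ties: more links into the module,
#' then lexicographic). P-values agreeing to 12 significant digits count
#' as tied, so last-bit differences in the tail computation cannot
#' reorder the expansion. Added nodes are reported in addition order as
#' ranks 1..\code{nAdded}. The \code{score} column is the addition
#' priority (\code{nAdded}, \code{nAdded - 1}, ..., 1), monotone with
#' rank as for every ranker; the hypergeometric p-value at the step of
#' addition is carried in the extra \code{neg_log10_p} column.
#'
#' @param network \code{igraph} undirected simple graph with named
#'   vertices.
#' @param seeds A \code{\linkS4class{SeedSet}} present in the network.
#' @param nAdded Number of nodes to add (at most the number of non-seed
#'   nodes).
#' @return A \code{\linkS4class{RankingTable}} (method \code{"diamond"})
#'   over the added nodes only.
#' @export
diamondRank <- function(network, seeds, nAdded) {
  stopifnot(is(seeds, "SeedSet"))
  ids <- igraph::V(network)$name
  if (!all(members(seeds) %in% ids))
    stop("seed(s) not in network: ",
         paste(setdiff(members(seeds), ids), collapse = ", "))
  nAdded <- as.integer(nAdded)
  if (nAdded < 0) stop("nAdded must be non-negative")
  candidates <- setdiff(ids, members(seeds))
  if (nAdded > length(candidates))
    stop("nAdded (", nAdded, ") exceeds the ", length(candidates),
         " non-seed nodes")
  N <- length(ids)
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- stats::setNames(Matrix::rowSums(A), ids)
  inModule <- stats::setNames(ids %in% members(seeds), ids)
  # ks: links from each node into the current module, updated incrementally
  ks <- stats::setNames(
    as.numeric(A %*% as.numeric(inModule)), ids)
  lexKey <- stats::setNames(match(ids, lexSort(ids)), ids)
  added <- character(nAdded)
  pAdded <- numeric(nAdded)
  for (step in seq_len(nAdded)) {
    cand <- ids[!inModule]
    p <- hyperTail(ks[cand], sum(inModule), N, deg[cand])
    # p-values that agree to 12 significant digits are treated as tied,
    # so last-bit noise in the tail sum cannot reorder the expansion
    pick <- cand[order(signif(p, 12), -ks[cand], lexKey[cand])][1L]
    added[step] <- pick
    pAdded[step] <- p[match(pick, cand)]
    inModule[pick] <- TRUE
    nbr <- ids[as.numeric(A[, pick]) > 0]
    ks[nbr] <- ks[nbr] + 1
  }
  df <- data.frame(node_id = added,
                   score = as.numeric(rev(seq_len(nAdded))),
                   rank = seq_len(nAdded),
                   is_seed = rep(FALSE, nAdded),
                   neg_log10_p = -log10(pmax(pAdded, .Machine$double.xmin)),
                   stringsAsFactors = FALSE)
  new("RankingTable", table = df, method = "diamond")
}
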