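## Planted seed-module benchmark networks. A two-block (or multi-block)
## stochastic block model emulates the structure the ranking method
## assumes: a seed community denser within itself than to the background.
## Part of the first block is handed out as seeds, the rest as held-out
## ground truth, so recovery can be scored without any real data.

#' Generate a planted seed-module network (stochastic block model)
#'
#' Draws one Bernoulli variable per unordered node pair: probability
#' \code{pIn} within a block, \code{pOut} between blocks. Pairs are
#' visited in node-index order (i < j), one \code{runif} draw each, under
#' a locally seeded Mersenne-Twister stream, so the edge set is fully
#' reproducible from \code{rngSeed}. All nodes are kept, including any
#' that end up isolated. A \code{seedFraction} of the first block is
#' returned as the seed set (a uniform sample; block members are
#' exchangeable) and the remainder of that block as held-out ground
#' truth. Identifiers are assigned to nodes by a seeded random
#' permutation, so lexicographic node order carries no information about
#' block membership (a ranker that merely sorts names gains nothing).
#'
#' @param blockSizes Integer vector of block sizes; the first block is
#'   the seed block.
#' @param pIn Within-block edge probability.
#' @param pOut Between-block edge probability (\code{pOut <= pIn}).
#' @param seedFraction Fraction of the first block used as seeds, (0, 1].
#' @param rngSeed Integer seed for the generator.
#' @return List with \code{network} (\code{igraph}), \code{seeds}
#'   (\code{\linkS4class{SeedSet}}), \code{heldOut} (character vector)
#'   and \code{block} (named integer vector of block memberships).
#' @export
#' @examples
#' net <- plantedNetwork(c(30, 120), pIn = 0.25, pOut = 0.02,
#'                       seedFraction = 1/3, rngSeed = 1)
#' igraph::vcount(net$network)  # 150
plantedNetwork <- function(blockSizes, pIn, pOut, seedFraction = 1/3,
                           rngSeed = 1L) {
  blockSizes <- as.integer(blockSizes)
  if (any(blockSizes < 1L)) stop("block sizes must be positive")
  if (pOut > pIn) stop("pOut must not exceed pIn")
  if (pIn < 0 || pIn > 1 || pOut < 0)
    stop("edge probabilities must lie in [0, 1]")
  if (seedFraction <= 0 || seedFraction > 1)
    stop("seedFraction must be in (0, 1]")
  n <- sum(blockSizes)
  block <- rep(seq_along(blockSizes), blockSizes)
  out <- withLocalSeed(rngSeed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    # upper.tri runs column-major: (1,2), (1,3), (2,3), ... = i < j order
    prob <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], pIn, pOut)
    hit <- stats::runif(nrow(pairs)) < prob
    nSeeds <- max(1L, round(seedFraction * blockSizes[1L]))
    seedIdx <- sort(sample(seq_len(blockSizes[1L]), nSeeds))
    # blind the identifiers: node index -> random label
    names <- sprintf("v%0*d", nchar(n), sample(n))
    list(pairs = pairs[hit, , drop = FALSE], seedIdx = seedIdx,
         names = names)
  })
  if (nrow(out$pairs) == 0L)
    stop("generated network has no edges; raise pIn/pOut or block sizes")
  ids <- out$names
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[out$pairs[, 1]], to = ids[out$pairs[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(ids), stringsAsFactors = FALSE))
  seedIds <- ids[out$seedIdx]
  heldOut <- setdiff(ids[seq_len(blockSizes[1L])], seedIds)
  list(network = g,
       seeds = seedSet(seedIds, name = "planted_block1"),
       heldOut = heldOut,
       block = stats::setNames(block, ids))
}

#' Small named fixture graphs
#'
#' Hard-coded graphs used across examples and tests:
#' \describe{
#'   \item{triangle}{Complete graph on a, b, c.}
#'   \item{path3}{Path a--b--c.}
#'   \item{star4}{Star with hub a and leaves b, c, d.}
#'   \item{two_blocks_tiny}{Two triangles (a1 a2 a3, b1 b2 b3) joined by
#'     the bridge a3--b1.}
#'   \item{diamond_demo}{The module-expansion demonstration graph:
#'     seeds s1, s2; candidate x adjacent to both seeds; candidate y
#'     adjacent to one seed and two background nodes u, v.}
#' }
#'
#' @param name Fixture name from the registry above.
#' @return An \code{igraph} graph. Fixtures with a designated seed set
#'   carry it in the \code{seeds} graph attribute (see
#'   \code{\link{fixtureSeeds}}).
#' @export
#' @examples
#' igraph::ecount(networkFixture("triangle"))  # 3
networkFixture <- function(name) {
  registry <- list(
    triangle = list(edges = c("a","b", "b","c", "a","c"), seeds = "a"),
    path3 = list(edges = c("a","b", "b","c"), seeds = "a"),
    star4 = list(edges = c("a","b", "a","c", "a","d"), seeds = "a"),
    two_blocks_tiny = list(
      edges = c("a1","a2", "a1","a3", "a2","a3",
                "b1","b2", "b1","b3", "b2","b3", "a3","b1"),
      seeds = c("a1", "a2")),
    diamond_demo = list(
      edges = c("s1","x", "s2","x", "s1","y", "y","u", "y","v", "u","v"),
      seeds = c("s1", "s2")))
  if (!name %in% names(registry))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  spec <- registry[[name]]
  em <- matrix(spec$edges, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::graph_attr(g, "seeds") <- spec$seeds
  g
}

#' Designated seed set of a fixture graph
#'
#' @param name Fixture name, see \code{\link{networkFixture}}.
#' @return A \code{\linkS4class{SeedSet}}.
#' @export
fixtureSeeds <- function(name) {
  g <- networkFixture(name)
  seedSet(igraph::graph_attr(g, "seeds"), name = name)
}
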