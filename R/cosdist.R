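## The core method: cosine similarity between centrality vectors, optional
## seed pruning, and mean-similarity ranking, plus the ranking-evaluation
## computations (seed-rank summaries, top-k compilation, cross-method
## overlap).

#' Cosine similarity of two vectors
#'
#' \eqn{\cos(u, v) = u \cdot v / (\|u\| \|v\|)}, in [-1, 1]: 1 for
#' identical directions, -1 for opposite, 0 for orthogonal. Undefined for
#' a zero-magnitude vector. Collinear vectors (Cauchy-Schwarz equality,
#' which floating arithmetic can only reach or overshoot when the vectors
#' are truly proportional) return exactly \code{1} or \code{-1}, so
#' self-similarity is exact.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number in [-1, 1].
#' @export
#' @examples
#' cosineSimilarity(c(1, 0), c(0, 1))  # 0
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  su <- sum(u^2); sv <- sum(v^2)
  if (su == 0 || sv == 0)
    stop("cosine similarity is undefined for a zero-magnitude vector")
  num <- sum(u * v)
  # Cauchy-Schwarz equality (collinear vectors) returned exactly as +/-1
  if (num * num >= su * sv) return(sign(num))
  num / sqrt(su * sv)
}

#' Row-wise cosine similarity matrix, with zero rows flagged
#' @noRd
cosineMatrix <- function(X, Y) {
  nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
  S <- tcrossprod(X, Y)
  S <- S / outer(nx, ny)
  S[S > 1] <- 1; S[S < -1] <- -1
  S  # rows/cols with zero norm come out NaN; callers decide the policy
}

#' Optionally z-score the feature columns before cosine
#'
#' Raw centralities span orders of magnitude, so cosine similarity is
#' dominated by the large-scale columns; per-column z-scoring makes the
#' ranking invariant to affine rescaling of any single measure. Constant
#' columns are left at 0.
#' @noRd
prepareFeatures <- function(matrix, zscore) {
  X <- as.matrix(matrix)
  if (!zscore) return(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sdv, "/")
}

#' Seed-to-seed cosine similarity table
#'
#' The pairwise cosine similarities among the seed vectors: a symmetric
#' matrix with unit diagonal, used to inspect seed coherence and to drive
#' optional seed pruning.
#'
#' @param matrix A \code{\linkS4class{CentralityMatrix}}.
#' @param seeds A \code{\linkS4class{SeedSet}} present in the matrix.
#' @param zscore Logical; z-score columns before cosine.
#' @return Symmetric numeric matrix, seeds x seeds, in seed input order.
#' @export
seedSimilarityMatrix <- function(matrix, seeds, zscore = FALSE) {
  stopifnot(is(matrix, "CentralityMatrix"), is(seeds, "SeedSet"))
  miss <- setdiff(members(seeds), nodeIds(matrix))
  if (length(miss))
    stop("seed(s) missing from centrality matrix: ",
         paste(miss, collapse = ", "))
  X <- prepareFeatures(matrix, zscore)[members(seeds), , drop = FALSE]
  S <- cosineMatrix(X, X)
  if (anyNA(S))
    stop("a seed has a zero-magnitude feature vector; ",
         "its similarity is undefined")
  diag(S) <- 1
  S
}

#' Prune seeds dissimilar to the rest of the set
#'
#' Removes every seed whose mean cosine similarity to the \emph{other}
#' seeds falls below \code{tau}: an optional cleanup step for seed sets
#' that mix structurally unrelated genes. At least one seed is always
#' retained — if all fall below the threshold the single most coherent
#' seed is kept with a warning.
#'
#' @inheritParams seedSimilarityMatrix
#' @param tau Similarity threshold in [-1, 1]. The default is the mean
#'   off-diagonal seed-seed similarity minus 2 standard deviations, a
#'   conservative outlier rule.
#' @return List with \code{seeds} (pruned \code{\linkS4class{SeedSet}})
#'   and \code{removed} (character vector).
#' @export
pruneSeeds <- function(matrix, seeds, tau = NULL, zscore = FALSE) {
  stopifnot(is(seeds, "SeedSet"))
  if (length(seeds) < 2L) {
    warning("fewer than 2 seeds; nothing to prune")
    return(list(seeds = seeds, removed = character()))
  }
  S <- seedSimilarityMatrix(matrix, seeds, zscore = zscore)
  off <- S[upper.tri(S) | lower.tri(S)]
  if (is.null(tau)) {
    tau <- mean(off) - 2 * stats::sd(off)
    if (is.na(tau)) tau <- -1  # two seeds: sd over a single value
  }
  if (tau < -1 || tau > 1) stop("tau must lie in [-1, 1]")
  meanOffSelf <- (rowSums(S) - 1) / (length(seeds) - 1)
  keep <- meanOffSelf >= tau - 1e-12   # guard the tau = 1 boundary
  if (!any(keep)) {
    warning("all seeds fall below tau = ", signif(tau, 4),
            "; keeping the single most coherent seed")
    best <- names(meanOffSelf)[order(-meanOffSelf,
                                     match(names(meanOffSelf),
                                           lexSort(names(meanOffSelf))))][1L]
    keep <- stats::setNames(names(meanOffSelf) == best, names(meanOffSelf))
  }
  kept <- members(seeds)[keep[members(seeds)]]
  removed <- setdiff(members(seeds), kept)
  list(seeds = new("SeedSet", name = setName(seeds), members = kept),
       removed = removed)
}

#' Mean cosine similarity of every node to the seed set
#'
#' For every node in the network (seeds included), the arithmetic mean of
#' its cosine similarities to each seed vector — the score that defines
#' the ranking. A node with a zero-magnitude feature vector (an isolated
#' node with all-zero centralities) cannot be placed in the cosine space;
#' it is assigned the minimum score -1 with a warning, a sink convention
#' that keeps the run alive rather than erroring it.
#'
#' @inheritParams seedSimilarityMatrix
#' @return A \code{\linkS4class{SimilarityScores}} over all nodes.
#' @export
meanSeedSimilarity <- function(matrix, seeds, zscore = FALSE) {
  stopifnot(is(matrix, "CentralityMatrix"), is(seeds, "SeedSet"))
  if (length(seeds) == 0L) stop("seed set is empty")
  miss <- setdiff(members(seeds), nodeIds(matrix))
  if (length(miss))
    stop("seed(s) missing from centrality matrix: ",
         paste(miss, collapse = ", "))
  X <- prepareFeatures(matrix, zscore)
  Sfull <- cosineMatrix(X, X[members(seeds), , drop = FALSE])
  if (anyNA(Sfull[members(seeds), ]))
    stop("a seed has a zero-magnitude feature vector")
  sc <- rowMeans(Sfull)
  zero <- !is.finite(sc)
  if (any(zero)) {
    warning(sum(zero), " node(s) with zero-magnitude feature vectors ",
            "assigned similarity -1: ",
            paste(utils::head(nodeIds(matrix)[zero], 5), collapse = ", "))
    sc[zero] <- -1
  }
  new("SimilarityScores", scores = stats::setNames(sc, nodeIds(matrix)))
}

#' Rank nodes by score
#'
#' Orders nodes by descending score; ties are broken lexicographically by
#' node identifier so output is deterministic. Seeds are included in the
#' ranking and flagged.
#'
#' @param scores A \code{\linkS4class{SimilarityScores}}, or any named
#'   numeric vector of per-node scores.
#' @param seeds A \code{\linkS4class{SeedSet}} used to set the seed flag.
#' @param method Ranker label recorded in the table.
#' @return A \code{\linkS4class{RankingTable}}.
#' @export
rankNodes <- function(scores, seeds, method = "cosdist") {
  if (is(scores, "SimilarityScores")) scores <- scores(scores)
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            is(seeds, "SeedSet"))
  ids <- names(scores)
  # match against the radix-sorted ids: a locale-independent tie-break key
  ord <- order(-scores, match(ids, lexSort(ids)))
  df <- data.frame(node_id = ids[ord],
                   score = unname(scores[ord]),
                   rank = seq_along(ids),
                   is_seed = ids[ord] %in% members(seeds),
                   stringsAsFactors = FALSE)
  new("RankingTable", table = df, method = method)
}

#' The full CentralityCosDist ranking in one call
#'
#' Convenience wrapper running the whole method: centrality features,
#' optional seed pruning, mean seed similarity, and ranking.
#'
#' @inheritParams computeCentralityMatrix
#' @param prune Logical; drop seeds dissimilar to the rest of the set.
#' @param tau Pruning threshold, see \code{\link{pruneSeeds}}.
#' @param zscore Logical; z-score feature columns before cosine.
#' @param ... Passed to \code{\link{computeCentralityMatrix}}.
#' @return A \code{\linkS4class{RankingTable}}.
#' @export
#' @examples
#' g <- networkFixture("triangle")
#' cosDistRank(g, seedSet("a"))
cosDistRank <- function(network, seeds, prune = FALSE, tau = NULL,
                        zscore = FALSE, ...) {
  cm <- computeCentralityMatrix(network, seeds, ...)
  if (prune && length(seeds) >= 2L)
    seeds <- pruneSeeds(cm, seeds, tau = tau, zscore = zscore)$seeds
  rankNodes(meanSeedSimilarity(cm, seeds, zscore = zscore), seeds)
}

#' First k rows of a ranking
#'
#' The per-method compilation cutoff; the conventional set size for
#' cross-method comparison is the top 10.
#'
#' @param ranking A \code{\linkS4class{RankingTable}}.
#' @param k Positive integer; if larger than the table, all rows.
#' @return A \code{\linkS4class{RankingTable}} with min(k, n) rows.
#' @export
topK <- function(ranking, k = 10L) {
  stopifnot(is(ranking, "RankingTable"))
  if (k < 1) stop("k must be >= 1")
  new("RankingTable",
      table = utils::head(ranking@table, k),
      method = ranking@method)
}

#' Where do the seeds themselves rank?
#'
#' Reports each seed's rank plus distribution summaries (median,
#' quartiles): a self-consistency check of the ranking. In leave-one-out
#' mode each seed's rank is recomputed from a ranking built without that
#' seed in the query set, removing the self-similarity advantage; LOO
#' needs the centrality matrix and at least two seeds.
#'
#' @param ranking A \code{\linkS4class{RankingTable}} (ignored in LOO
#'   mode, which re-ranks internally).
#' @param seeds A \code{\linkS4class{SeedSet}}.
#' @param loo Logical; leave-one-out evaluation.
#' @param matrix \code{\linkS4class{CentralityMatrix}}, required when
#'   \code{loo = TRUE}.
#' @param zscore Passed to the re-ranking in LOO mode.
#' @return List with \code{ranks} (named integer vector per seed) and
#'   \code{summary} (median, q25, q75, min, max, n).
#' @export
evaluateSeedRanks <- function(ranking, seeds, loo = FALSE, matrix = NULL,
                              zscore = FALSE) {
  stopifnot(is(seeds, "SeedSet"))
  if (loo) {
    if (is.null(matrix))
      stop("leave-one-out evaluation needs the centrality matrix")
    if (length(seeds) < 2L)
      stop("leave-one-out evaluation needs at least 2 seeds")
    ranks <- vapply(members(seeds), function(s) {
      rest <- new("SeedSet", name = setName(seeds),
                  members = setdiff(members(seeds), s))
      rt <- rankNodes(meanSeedSimilarity(matrix, rest, zscore = zscore),
                      rest)
      rt@table$rank[rt@table$node_id == s]
    }, integer(1))
  } else {
    stopifnot(is(ranking, "RankingTable"))
    tb <- ranking@table
    miss <- setdiff(members(seeds), tb$node_id)
    if (length(miss))
      stop("seed(s) absent from ranking: ", paste(miss, collapse = ", "))
    ranks <- stats::setNames(
      tb$rank[match(members(seeds), tb$node_id)], members(seeds))
  }
  q <- stats::quantile(ranks, c(0.25, 0.5, 0.75), type = 7)
  list(ranks = ranks,
       summary = c(median = unname(q[2]), q25 = unname(q[1]),
                   q75 = unname(q[3]), min = min(ranks), max = max(ranks),
                   n = length(ranks)))
}

#' Pairwise top-k overlap between rankings
#'
#' For every pair of rankers, the number of nodes shared by their top-k
#' sets — the quantity a chord diagram of method agreement displays.
#' Externally produced rankings read with \code{\link{readRankingTable}}
#' plug in alongside the package's own rankers.
#'
#' @param rankings Named list of \code{\linkS4class{RankingTable}}s
#'   (unnamed entries take their recorded method label).
#' @param k Top-set size.
#' @return Symmetric integer matrix of overlap counts; the diagonal holds
#'   each method's own top-set size.
#' @export
topKOverlap <- function(rankings, k = 10L) {
  if (length(rankings) < 2L) stop("need at least 2 rankings")
  if (k < 1) stop("k must be >= 1")
  nms <- names(rankings)
  if (is.null(nms)) nms <- rep("", length(rankings))
  nms[nms == ""] <- vapply(rankings[nms == ""], rankerMethod, "")
  if (anyDuplicated(nms))
    nms <- make.unique(nms)
  tops <- lapply(rankings, function(r) nodeIds(topK(r, k)))
  m <- matrix(0L, length(tops), length(tops), dimnames = list(nms, nms))
  for (i in seq_along(tops))
    for (j in seq_along(tops))
      m[i, j] <- length(intersect(tops[[i]], tops[[j]]))
  m
}
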