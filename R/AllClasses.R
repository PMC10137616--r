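#' Canonical centrality measure order
#'
#' The fixed, documented column order of the node feature space. The
#' eigenvector measure appears twice (as \code{eigenvector} and
#' \code{eigenvector_dup}) so that default node vectors are 9-dimensional;
#' see \code{\link{computeCentralityMatrix}} for the rationale and for a
#' switch that deduplicates to 8 dimensions.
#'
#' @return Character vector of the nine default measure labels, in order.
#' @export
#' @examples
#' centralityMeasures()
centralityMeasures <- function() {
  c("degree", "betweenness", "closeness", "eigenvector", "pagerank",
    "personalized_pagerank", "information", "eigenvector_dup",
    "clustering_coefficient")
}

#' SeedSet: a named, ordered set of query nodes
#'
#' Holds the seed genes/proteins anchoring a prioritization run. Members
#' are unique node identifiers; their order is preserved from the input
#' file and used only for deterministic reporting.
#'
#' @slot name Single character label for the set (e.g. the seed file stem).
#' @slot members Character vector of unique node identifiers.
#'
#' @exportClass SeedSet
setClass("SeedSet",
  representation(name = "character", members = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L || is.na(object@name))
      msg <- c(msg, "'name' must be a single non-NA string")
    if (anyDuplicated(object@members))
      msg <- c(msg, "seed members must be unique")
    if (length(object@members) > 0 && any(is.na(object@members) | object@members == ""))
      msg <- c(msg, "seed members must be non-empty strings")
    if (is.null(msg)) TRUE else msg
  })

#' CentralityMatrix: node-by-measure feature space
#'
#' A real matrix with one row per network node (lexicographic order) and
#' one named column per centrality measure. All entries are finite.
#'
#' @slot values Numeric matrix; rownames are node identifiers, colnames
#'   measure labels.
#'
#' @exportClass CentralityMatrix
setClass("CentralityMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    msg <- NULL
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must carry node (row) and measure (column) names")
    else {
      if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate node identifiers")
      if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate measure labels")
      if (!identical(rownames(v), sort(rownames(v), method = "radix")))
        msg <- c(msg, "rows must be in lexicographic node order")
    }
    if (is.numeric(v) && length(v) && !all(is.finite(v)))
      msg <- c(msg, "all centrality values must be finite")
    if (ncol(v) < 1L) msg <- c(msg, "at least one measure column required")
    if (is.null(msg)) TRUE else msg
  })

#' SimilarityScores: per-node mean cosine similarity to the seed set
#'
#' @slot scores Named numeric vector, one finite score in [-1, 1] per node.
#'
#' @exportClass SimilarityScores
setClass("SimilarityScores",
  representation(scores = "numeric"),
  validity = function(object) {
    s <- object@scores
    msg <- NULL
    if (is.null(names(s)) || anyDuplicated(names(s)))
      msg <- c(msg, "scores must be uniquely named by node")
    if (!all(is.finite(s)))
      msg <- c(msg, "all scores must be finite")
    else if (any(s < -1 - 1e-9 | s > 1 + 1e-9))
      msg <- c(msg, "scores must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' RankingTable: an ordered node prioritization
#'
#' Common output of every ranker. Ranks are 1..n with no gaps, scores are
#' non-increasing with rank, and ties are broken lexicographically by node
#' identifier so output is bit-reproducible.
#'
#' @slot table data.frame with columns \code{node_id}, \code{score},
#'   \code{rank}, \code{is_seed}.
#' @slot method Character label naming the ranker that produced the table.
#'
#' @exportClass RankingTable
setClass("RankingTable",
  representation(table = "data.frame", method = "character"),
  validity = function(object) {
    tb <- object@table
    msg <- NULL
    need <- c("node_id", "score", "rank", "is_seed")
    if (!all(need %in% names(tb)))
      return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tb)) {
      if (!all(tb$rank == seq_len(nrow(tb))))
        msg <- c(msg, "ranks must be 1..n in order")
      if (any(diff(tb$score) > 1e-12))
        msg <- c(msg, "scores must be non-increasing with rank")
      if (anyDuplicated(tb$node_id)) msg <- c(msg, "duplicate node_id")
    }
    if (length(object@method) != 1L) msg <- c(msg, "'method' must be length 1")
    if (is.null(msg)) TRUE else msg
  })

#' ClusterLabels: unsupervised node labels from centrality space
#'
#' @slot labels Named integer vector, one label per node; -1 marks noise
#'   points under density clustering.
#' @slot method Label source, \code{"dbscan"} or \code{"kmeans"}.
#' @slot params List of the clustering parameters actually used (recorded
#'   for reproducibility, including any random seed).
#'
#' @exportClass ClusterLabels
setClass("ClusterLabels",
  representation(labels = "integer", method = "character", params = "list"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
      msg <- c(msg, "labels must be uniquely named by node")
    if (any(is.na(object@labels))) msg <- c(msg, "labels must be non-NA")
    if (length(object@method) != 1L) msg <- c(msg, "'method' must be length 1")
    if (is.null(msg)) TRUE else msg
  })

#' ImportanceReport: permutation importance of each centrality
#'
#' Mean accuracy drop of a random-forest classifier (cluster labels as
#' target) when one centrality column is shuffled, over a recorded number
#' of repeats, plus the spread over repeats. Seeds and forest size are
#' recorded so the report is bit-reproducible.
#'
#' @slot importance Named numeric vector, mean accuracy drop per measure.
#' @slot importanceSd Named numeric vector, sd of the drop over repeats.
#' @slot method Clustering source the labels came from.
#' @slot baselineAccuracy Held-out accuracy of the unshuffled model.
#' @slot nTrees Number of trees in the forest.
#' @slot nRepeats Number of shuffles per feature.
#' @slot seed Integer RNG seed used throughout.
#'
#' @exportClass ImportanceReport
setClass("ImportanceReport",
  representation(importance = "numeric", importanceSd = "numeric",
                 method = "character", baselineAccuracy = "numeric",
                 nTrees = "integer", nRepeats = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@importance)))
      msg <- c(msg, "importance must be named by measure")
    if (!identical(names(object@importance), names(object@importanceSd)))
      msg <- c(msg, "importance and importanceSd must share names")
    if (length(object@method) != 1L) msg <- c(msg, "'method' must be length 1")
    if (is.null(msg)) TRUE else msg
  })
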