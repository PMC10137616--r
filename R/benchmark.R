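## Benchmark studies on synthetic data: planted-module recovery for the
## ranking method, and a sanity study for the permutation-importance
## machinery. These are the package's stand-ins for real-network
## evaluations: every quantity is computed from generated inputs, so the
## studies are fully reproducible from their seeds.

#' Planted-module recovery study
#'
#' Repeatedly generates a planted seed-module network (two-block
#' stochastic block model), ranks all nodes by mean cosine similarity to
#' a seed subset of the first block, and asks where the held-out first
#' block members land among the non-seed nodes. A replicate counts as a
#' success when the median held-out rank falls within the top
#' \code{topFraction} of non-seed nodes. A degenerate comparator that
#' simply orders non-seed nodes lexicographically is scored on the same
#' statistic; with blinded node labels it has no signal to exploit.
#'
#' @param nReplicates Number of generated networks.
#' @param blockSizes,pIn,pOut,seedFraction Passed to
#'   \code{\link{plantedNetwork}}; defaults are the reference study
#'   conditions (blocks 30/120, within-block edge probability 0.25,
#'   between-block 0.02, a third of the first block as seeds).
#' @param topFraction Success cutoff as a fraction of non-seed nodes.
#' @param baseSeed Generator seed of replicate i is
#'   \code{baseSeed + i - 1}.
#' @param zscore Passed to the ranker.
#' @return data.frame with one row per replicate: the median held-out
#'   rank among non-seed nodes for the cosine ranker
#'   (\code{medianRank}) and the lexicographic comparator
#'   (\code{lexMedianRank}), the number of non-seed nodes \code{nonSeed},
#'   and logical \code{success} / \code{lexSuccess} flags.
#' @export
plantedRecoveryStudy <- function(nReplicates = 50L,
                                 blockSizes = c(30L, 120L), pIn = 0.25,
                                 pOut = 0.02, seedFraction = 1/3,
                                 topFraction = 0.2, baseSeed = 1L,
                                 zscore = FALSE) {
  rows <- lapply(seq_len(nReplicates), function(i) {
    pn <- plantedNetwork(blockSizes, pIn, pOut, seedFraction,
                         rngSeed = baseSeed + i - 1L)
    rk <- suppressWarnings(cosDistRank(pn$network, pn$seeds,
                                       zscore = zscore))
    tb <- as.data.frame(rk)
    nonSeed <- tb$node_id[!tb$is_seed]   # already in rank order
    pos <- match(pn$heldOut, nonSeed)
    lexPos <- match(pn$heldOut, sort(nonSeed, method = "radix"))
    cutoff <- topFraction * length(nonSeed)
    data.frame(replicate = i,
               medianRank = stats::median(pos),
               lexMedianRank = stats::median(lexPos),
               nonSeed = length(nonSeed),
               success = stats::median(pos) <= cutoff,
               lexSuccess = stats::median(lexPos) <= cutoff)
  })
  do.call(rbind, rows)
}

#' Permutation-importance sanity study
#'
#' Repeatedly builds a synthetic feature matrix in which exactly one
#' column (named \code{degree}) determines a binary label (above/below
#' its median) while the remaining columns are independent noise and one
#' column is constant, then runs \code{\link{permutationImportance}}.
#' Reports, per replicate, whether the label-defining column received
#' the maximum importance and the (exactly zero) importance of the
#' constant column.
#'
#' @param nReplicates Number of seeded replicates.
#' @param nNodes Rows of the synthetic feature matrix.
#' @param nNoise Number of noise feature columns.
#' @param nTrees,nRepeats Forest size and shuffles per feature.
#' @param baseSeed Replicate i uses seed \code{baseSeed + i - 1}.
#' @return data.frame with columns \code{replicate}, \code{topMeasure},
#'   \code{degreeIsTop}, \code{constantImportance}.
#' @export
importanceSanityStudy <- function(nReplicates = 20L, nNodes = 200L,
                                  nNoise = 5L, nTrees = 500L,
                                  nRepeats = 10L, baseSeed = 1L) {
  noiseNames <- c("betweenness", "closeness", "eigenvector", "pagerank",
                  "information", "clustering_coefficient")
  stopifnot(nNoise <= length(noiseNames))
  rows <- lapply(seq_len(nReplicates), function(i) {
    seed <- baseSeed + i - 1L
    vals <- withLocalSeed(seed, {
      cbind(matrix(stats::runif(nNodes), ncol = 1),
            matrix(stats::rnorm(nNodes * nNoise), nNodes, nNoise),
            matrix(1, nNodes, 1))
    })
    colnames(vals) <- c("degree", noiseNames[seq_len(nNoise)], "constant")
    rownames(vals) <- sprintf("g%0*d", nchar(nNodes), seq_len(nNodes))
    cm <- new("CentralityMatrix", values = vals)
    lab <- as.integer(vals[, "degree"] > stats::median(vals[, "degree"])) + 1L
    cl <- new("ClusterLabels",
              labels = stats::setNames(lab, rownames(vals)),
              method = "synthetic", params = list(seed = seed))
    rep <- permutationImportance(cm, cl, nTrees = nTrees,
                                 nRepeats = nRepeats, seed = seed)
    imp <- importance(rep)
    data.frame(replicate = i,
               topMeasure = names(which.max(imp)),
               degreeIsTop = names(which.max(imp)) == "degree",
               constantImportance = unname(imp["constant"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
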