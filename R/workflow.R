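## The assembled workflow: one call (or one CLI invocation) from an
## edge list + seed file to the full set of tabular outputs, with a
## manifest that suffices to re-run the identical analysis.

#' Workflow configuration with documented defaults
#'
#' All tunable settings of the workflow in one validated list. Unknown
#' keys are rejected, so a typo in a config file fails loudly instead of
#' silently running defaults.
#'
#' @param weighted Use the edge weight column (default FALSE: all
#'   centralities on the unweighted topology).
#' @param dedupeEigenvector Drop the duplicated eigenvector column,
#'   giving 8-dimensional node vectors instead of the default 9.
#' @param zscore Z-score feature columns before cosine similarity
#'   (default FALSE: cosine on raw centrality vectors).
#' @param prune Enable seed pruning (default FALSE).
#' @param tau Seed-pruning threshold; NULL = mean off-diagonal seed-seed
#'   similarity minus 2 sd.
#' @param topK Compilation cutoff (default 10).
#' @param damping PageRank damping (default 0.85).
#' @param restart RWR restart probability (default 0.5).
#' @param rwrTol,rwrMaxIter RWR convergence controls.
#' @param nAdded Module-expansion step count for the DIAMOnD-style
#'   baseline (default 100).
#' @param cluster Clustering method for the importance analysis.
#' @param k,eps,minPts Clustering parameters (see
#'   \code{\link{clusterNodes}}).
#' @param nTrees,nRepeats Random-forest size and shuffle repeats.
#' @param seed RNG seed for clustering/forest/shuffles (default 0).
#' @return Named list of class \code{ccd_config}.
#' @export
ccdConfig <- function(weighted = FALSE, dedupeEigenvector = FALSE,
                      zscore = FALSE, prune = FALSE, tau = NULL,
                      topK = 10L, damping = 0.85, restart = 0.5,
                      rwrTol = 1e-10, rwrMaxIter = 10000L, nAdded = 100L,
                      cluster = "kmeans", k = 4L, eps = NULL,
                      minPts = 5L, nTrees = 500L, nRepeats = 10L,
                      seed = 0L) {
  cfg <- list(weighted = isTRUE(weighted),
              dedupeEigenvector = isTRUE(dedupeEigenvector),
              zscore = isTRUE(zscore), prune = isTRUE(prune), tau = tau,
              topK = as.integer(topK), damping = damping,
              restart = restart, rwrTol = rwrTol,
              rwrMaxIter = as.integer(rwrMaxIter),
              nAdded = as.integer(nAdded), cluster = cluster,
              k = as.integer(k), eps = eps, minPts = as.integer(minPts),
              nTrees = as.integer(nTrees),
              nRepeats = as.integer(nRepeats), seed = as.integer(seed))
  class(cfg) <- "ccd_config"
  cfg
}

#' Load a workflow configuration from a YAML file
#'
#' Keys present in the file override the defaults of
#' \code{\link{ccdConfig}}; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A \code{ccd_config} list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(ccdConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(ccdConfig, vals)
}

#' Run the full prioritization workflow
#'
#' Loads the network and seeds, computes the centrality matrix and
#' seed-seed similarity, optionally prunes the seeds, ranks all nodes by
#' mean cosine similarity, and writes every table plus a manifest
#' (config, input checksums, package version) to \code{outDir}.
#' Deterministic: identical inputs and config give byte-identical
#' outputs (manifest timestamp aside).
#'
#' @param networkPath Edge-list (or, with \code{graphml = TRUE}, GraphML)
#'   file.
#' @param seedsPath Seed list, one identifier per line.
#' @param outDir Output directory, created if needed.
#' @param config A \code{ccd_config} list, see \code{\link{ccdConfig}}.
#' @param graphml Logical; read \code{networkPath} as GraphML.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named character vector of the files written.
#' @export
runWorkflow <- function(networkPath, seedsPath, outDir,
                        config = ccdConfig(), graphml = FALSE,
                        quiet = FALSE) {
  stopifnot(inherits(config, "ccd_config"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("loading network: ", networkPath)
  net <- if (graphml) loadGraphML(networkPath, quiet = quiet)
         else loadEdgeList(networkPath, weighted = config$weighted,
                           quiet = quiet)
  say("loading seeds: ", seedsPath)
  sl <- loadSeeds(seedsPath, net, quiet = quiet)
  seeds <- sl$seeds

  say("computing centrality matrix (", igraph::vcount(net), " nodes)")
  cm <- computeCentralityMatrix(net, seeds, weighted = config$weighted,
                                dedupeEigenvector = config$dedupeEigenvector,
                                damping = config$damping)
  files <- c(centrality_matrix = file.path(outDir, "centrality_matrix.tsv"))
  writeResultTable(cm, files["centrality_matrix"])

  ss <- seedSimilarityMatrix(cm, seeds, zscore = config$zscore)
  files["seed_similarity"] <- file.path(outDir, "seed_similarity.tsv")
  writeResultTable(data.frame(seed = rownames(ss), ss, check.names = FALSE,
                              stringsAsFactors = FALSE),
                   files["seed_similarity"])

  if (config$prune && length(seeds) >= 2L) {
    pr <- pruneSeeds(cm, seeds, tau = config$tau, zscore = config$zscore)
    seeds <- pr$seeds
    say("seed pruning removed ", length(pr$removed), " seed(s)")
    files["pruned_seeds"] <- file.path(outDir, "pruned_seeds.txt")
    writeLines(members(seeds), files["pruned_seeds"])
  }

  ranking <- rankNodes(meanSeedSimilarity(cm, seeds,
                                          zscore = config$zscore), seeds)
  files["ranking"] <- file.path(outDir, "ranking.tsv")
  writeResultTable(ranking, files["ranking"])
  files["top_k"] <- file.path(outDir, "top_k.tsv")
  writeResultTable(topK(ranking, config$topK), files["top_k"])

  manifest <- list(
    version = as.character(utils::packageVersion("CentralityCosDist")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(
      network = list(path = normalizePath(networkPath),
                     md5 = unname(tools::md5sum(networkPath))),
      seeds = list(path = normalizePath(seedsPath),
                   md5 = unname(tools::md5sum(seedsPath))),
      seeds_used = members(seeds),
      seeds_missing = sl$missing),
    config = unclass(config))
  files["manifest"] <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest, files["manifest"])
  say("wrote ", length(files), " files to ", outDir)
  invisible(files)
}
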