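test_that("cosine similarity identities and bounds", {
  v <- c(0.3, 1.7, 2.2, 0.01)
  expect_identical(cosineSimilarity(v, v), 1)
  expect_identical(cosineSimilarity(v, -v), -1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero-magnitude")
  expect_error(cosineSimilarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("cosine is invariant to positive rescaling of either vector", {
  withr::with_seed(1, {
    for (i in 1:20) {
      u <- rnorm(6); v <- rnorm(6)
      a <- runif(1, 1e-6, 1e6)
      expect_equal(cosineSimilarity(a * u, v), cosineSimilarity(u, v),
                   tolerance = 1e-12)
      expect_true(abs(cosineSimilarity(u, v)) <= 1)
    }
  })
})

test_that("seed-seed similarity table is symmetric with unit diagonal", {
  vals <- rbind(s1 = c(1, 0, 2), s2 = c(1, 0, 2), s3 = c(0, 1, 0),
                n1 = c(2, 2, 2))
  colnames(vals) <- c("f1", "f2", "f3")
  cm <- cmFromMatrix(vals)
  S <- seedSimilarityMatrix(cm, seedSet(c("s1", "s2")))
  expect_equal(S, matrix(1, 2, 2, dimnames = list(c("s1", "s2"),
                                                  c("s1", "s2"))))
  S2 <- seedSimilarityMatrix(cmFromMatrix(rbind(a = c(1, 0), b = c(0, 1))),
                             seedSet(c("a", "b")))
  expect_equal(S2["a", "b"], 0)
  withr::with_seed(2, {
    vals <- matrix(rnorm(40), 8, 5,
                   dimnames = list(letters[1:8], paste0("f", 1:5)))
    S3 <- seedSimilarityMatrix(cmFromMatrix(vals), seedSet(letters[1:5]))
    expect_equal(S3, t(S3))
    expect_equal(unname(diag(S3)), rep(1, 5))
  })
  expect_error(seedSimilarityMatrix(cmFromMatrix(rbind(a = 1, b = 2)),
                                    seedSet("zz")), "missing")
})

test_that("seed pruning removes outliers but never empties the set", {
  vals <- rbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(0, 1), n = c(1, 1))
  colnames(vals) <- c("f1", "f2")
  cm <- cmFromMatrix(vals)
  seeds <- seedSet(c("s1", "s2", "s3"))
  # s3 has mean off-self similarity 0 < 0.5; s1/s2 have 0.5 each
  res <- pruneSeeds(cm, seeds, tau = 0.5)
  expect_equal(members(res$seeds), c("s1", "s2"))
  expect_equal(res$removed, "s3")

  expect_equal(members(pruneSeeds(cm, seeds, tau = -1)$seeds),
               members(seeds))

  same <- cmFromMatrix(rbind(s1 = c(1, 2), s2 = c(1, 2), s3 = c(2, 4)))
  expect_length(pruneSeeds(same, seedSet(c("s1", "s2", "s3")),
                           tau = 1)$removed, 0)

  expect_warning(one <- pruneSeeds(cm, seedSet("s1"), tau = 0.5),
                 "nothing to prune")
  expect_equal(members(one$seeds), "s1")

  orth <- cmFromMatrix(rbind(s1 = c(1, 0), s2 = c(0, 1)))
  expect_warning(kept <- pruneSeeds(orth, seedSet(c("s1", "s2")),
                                    tau = 0.9), "most coherent")
  expect_length(members(kept$seeds), 1)
})

test_that("mean seed similarity matches hand computation", {
  vals <- rbind(s1 = c(1, 0), s2 = c(0, 1), n1 = c(1, 1))
  colnames(vals) <- c("f1", "f2")
  cm <- cmFromMatrix(vals)
  sc <- scores(meanSeedSimilarity(cm, seedSet(c("s1", "s2"))))
  expect_equal(unname(sc["n1"]), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(sc["s1"]), (1 + 0) / 2)

  one <- scores(meanSeedSimilarity(cm, seedSet("s1")))
  expect_equal(unname(one["s1"]), 1)

  # a seed scores at least the mean of its similarities to the others
  withr::with_seed(4, {
    vals <- matrix(abs(rnorm(60)), 10, 6,
                   dimnames = list(letters[1:10], paste0("f", 1:6)))
    cm <- cmFromMatrix(vals)
    seeds <- seedSet(letters[1:4])
    S <- seedSimilarityMatrix(cm, seeds)
    sc <- scores(meanSeedSimilarity(cm, seeds))
    for (s in letters[1:4]) {
      others <- setdiff(letters[1:4], s)
      expect_gte(sc[[s]], mean(S[s, others]) - 1e-12)
    }
  })
  expect_error(meanSeedSimilarity(cm, seedSet("nope")), "missing")
})

test_that("zero-magnitude node vectors sink to -1 with a warning", {
  vals <- rbind(a = c(1, 1), b = c(0, 0), c = c(2, 2))
  colnames(vals) <- c("f1", "f2")
  expect_warning(sc <- meanSeedSimilarity(cmFromMatrix(vals), seedSet("a")),
                 "zero-magnitude")
  expect_equal(unname(scores(sc)["b"]), -1)
  expect_equal(unname(scores(sc)["c"]), 1)
  # zero-vector *seed* is an error, not a warning
  expect_error(meanSeedSimilarity(cmFromMatrix(vals), seedSet("b")),
               "zero-magnitude")
})

test_that("ranking orders by score with lexicographic tie-break", {
  rt <- rankNodes(c(a = 0.9, b = 0.5, c = 0.9), seedSet("a"))
  tb <- as.data.frame(rt)
  expect_equal(tb$node_id, c("a", "c", "b"))
  expect_equal(tb$rank, 1:3)
  expect_equal(tb$is_seed, c(TRUE, FALSE, FALSE))

  tied <- rankNodes(c(z = 1, q = 1, m = 1), seedSet("q"))
  expect_equal(nodeIds(tied), c("m", "q", "z"))

  withr::with_seed(6, {
    sc <- stats::setNames(round(runif(40), 1), sprintf("g%02d", 1:40))
    tb <- as.data.frame(rankNodes(sc, seedSet("g01")))
    expect_equal(tb$rank, 1:40)
    expect_true(all(diff(tb$score) <= 0))
  })
})

test_that("top-k compilation returns min(k, n) rows, default 10", {
  withr::with_seed(8, sc <- stats::setNames(runif(50), sprintf("g%02d", 1:50)))
  rk <- rankNodes(sc, seedSet("g01"))
  expect_equal(length(topK(rk)), 10)
  expect_equal(length(topK(rk, 60)), 50)
  expect_equal(as.data.frame(topK(rk, 50)), as.data.frame(rk))
  expect_error(topK(rk, 0), ">= 1")
})

test_that("seed-rank evaluation reports ranks and summaries", {
  sc <- stats::setNames(seq(1, 0.1, length.out = 10), letters[1:10])
  rk <- rankNodes(sc, seedSet(c("a", "b", "c")))
  ev <- evaluateSeedRanks(rk, seedSet(c("a", "b", "c")))
  expect_equal(unname(ev$ranks), c(1, 2, 3))
  expect_equal(unname(ev$summary["median"]), 2)
  ev1 <- evaluateSeedRanks(rk, seedSet("a"))
  expect_equal(unname(ev1$summary["median"]), 1)
  expect_error(evaluateSeedRanks(rk, seedSet("zz")), "absent")
})

test_that("leave-one-out: identical seed vectors keep held-out seeds on top", {
  vals <- rbind(s1 = c(2, 1), s2 = c(2, 1), s3 = c(2, 1),
                u = c(1, 2), v = c(0.5, 3))
  colnames(vals) <- c("f1", "f2")
  cm <- cmFromMatrix(vals)
  seeds <- seedSet(c("s1", "s2", "s3"))
  ev <- evaluateSeedRanks(NULL, seeds, loo = TRUE, matrix = cm)
  expect_true(all(ev$ranks <= 3))  # never below the distinct-direction nodes
  expect_error(evaluateSeedRanks(NULL, seedSet("s1"), loo = TRUE,
                                 matrix = cm), "at least 2")
})

test_that("top-k overlap counts shared nodes per method pair", {
  sc1 <- stats::setNames(seq(1, 0.05, length.out = 20), letters[1:20])
  r1 <- rankNodes(sc1, seedSet("a"), method = "m1")
  ov <- topKOverlap(list(r1, r1), k = 10)
  expect_equal(unname(ov[1, 2]), 10)

  sc2 <- stats::setNames(seq(1, 0.05, length.out = 20), rev(letters[1:20]))
  r2 <- rankNodes(sc2, seedSet("a"), method = "m2")
  expect_equal(unname(topKOverlap(list(r1, r2), k = 10)[1, 2]), 0)

  # exactly {a, b} shared in the top-3
  r3 <- rankNodes(c(a = 3, b = 2, x = 1, c = 0.5), seedSet("a"), "m3")
  r4 <- rankNodes(c(a = 3, b = 2, y = 1, c = 0.5), seedSet("a"), "m4")
  ov2 <- topKOverlap(list(r3, r4), k = 3)
  expect_equal(unname(ov2["m3", "m4"]), 2)
  expect_equal(ov2, t(ov2))
  expect_error(topKOverlap(list(r1), k = 10), "at least 2")
  expect_error(topKOverlap(list(r1, r2), k = 0), ">= 1")
})

test_that("z-scoring makes the ranking invariant to per-column rescaling", {
  pn <- plantedNetwork(c(10, 20), 0.5, 0.1, 0.5, rngSeed = 3)
  cm <- computeCentralityMatrix(pn$network, pn$seeds)
  vals <- as.matrix(cm)
  scaled <- vals
  scaled[, "degree"] <- scaled[, "degree"] * 1000 + 5
  scaled[, "pagerank"] <- scaled[, "pagerank"] * 0.001
  cmScaled <- cmFromMatrix(scaled)

  zs1 <- rankNodes(meanSeedSimilarity(cm, pn$seeds, zscore = TRUE),
                   pn$seeds)
  zs2 <- rankNodes(meanSeedSimilarity(cmScaled, pn$seeds, zscore = TRUE),
                   pn$seeds)
  expect_equal(nodeIds(zs1), nodeIds(zs2))
  expect_equal(scores(zs1), scores(zs2), tolerance = 1e-9)

  # whereas raw cosine is documented to be scale-sensitive: the scores move
  raw1 <- scores(meanSeedSimilarity(cm, pn$seeds))
  raw2 <- scores(meanSeedSimilarity(cmScaled, pn$seeds))
  expect_gt(max(abs(raw1 - raw2)), 1e-6)
})
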