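# Network construction: weights, soft power selection, transition matrix,
# global similarity.

test_that("weight matrix follows |cor|^beta with hard cutoff and clamping", {
  # two genes with identical profiles: |cor| = 1, clamped into [0, 1)
  base <- c(1, 2, 3, 4, 5, 7, 6, 9, 8, 10)
  x <- rbind(gA = base, gB = base, gC = rev(base) + rnorm(10, sd = 0.1))
  net <- buildCoexNetwork(x, networkBuildConfig(beta = 6, tau = 0.1))
  expect_lt(weightMatrix(net)["gA", "gB"], 1)
  expect_gt(weightMatrix(net)["gA", "gB"], 1 - 1e-9)
  expect_true("gA|gB" %in% edgeSet(net))

  # derived: random 5-gene matrix must reproduce the formula applied to
  # independently computed correlations
  set.seed(41)
  y <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  cfg <- networkBuildConfig(beta = 2, tau = 0.3)
  net2 <- buildCoexNetwork(y, cfg)
  expected <- abs(stats::cor(t(y)))^2
  expected[expected < 0.3] <- 0
  diag(expected) <- 0
  expect_equal(unname(weightMatrix(net2)), unname(expected), tolerance = 1e-12)
})

test_that("zero-variance genes are isolated with a warning, not dropped", {
  x <- rbind(gA = rnorm(10), gB = rnorm(10), gC = rep(2, 10))
  expect_warning(net <- buildCoexNetwork(x, networkBuildConfig(beta = 2, tau = 0)),
                 "zero-variance")
  expect_identical(geneIDs(net), c("gA", "gB", "gC"))
  expect_true(all(weightMatrix(net)["gC", ] == 0))
  expect_true(all(transitionMatrix(net)["gC", ] == 0))
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  expect_error(buildCoexNetwork(x), "3 samples")
  expect_error(buildCoexNetwork(matrix(rnorm(8), 2, 4,
                                       dimnames = list(c("a", "b"), NULL))),
               "3 genes")
})

test_that("transition matrix normalises rows and zeroes isolated nodes", {
  ids <- c("i", "u", "v", "z")
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W["i", "u"] <- W["u", "i"] <- 0.2
  W["i", "v"] <- W["v", "i"] <- 0.3
  M <- transitionMatrix(W)
  expect_equal(unname(M["i", c("u", "v")]), c(0.4, 0.6))
  expect_true(all(M["z", ] == 0))  # isolated: all-zero row
  expect_error(transitionMatrix(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")

  # random 8-node network: rows sum to 1, and M is generally asymmetric
  set.seed(7)
  W8 <- randW(8, p = 0.5)
  M8 <- transitionMatrix(W8)
  expect_equal(unname(rowSums(M8)[rowSums(W8) > 0]),
               rep(1, sum(rowSums(W8) > 0)), tolerance = 1e-12)
  expect_equal(M8, W8 / rowSums(W8), tolerance = 1e-12)  # direct summation
  expect_false(isSymmetric(M8))
})

test_that("equal-weight neighbourhoods give uniform transition probabilities", {
  set.seed(11)
  W <- randW(10, p = 0.4)
  W[W > 0] <- 0.37
  M <- transitionMatrix(W)
  deg <- rowSums(W > 0)
  for (i in which(deg > 0))
    expect_equal(unname(M[i, W[i, ] > 0]), rep(1 / unname(deg[i]), deg[i]))
})

test_that("raising tau or beta never densifies the network", {
  set.seed(21)
  x <- matrix(rnorm(300), 30, 10, dimnames = list(sprintf("g%02d", 1:30), NULL))
  taus <- c(0, 0.1, 0.3, 0.6)
  counts <- vapply(taus, function(tau)
    length(edgeSet(buildCoexNetwork(x, networkBuildConfig(beta = 3, tau = tau)))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  w2 <- weightMatrix(buildCoexNetwork(x, networkBuildConfig(beta = 2, tau = 0)))
  w5 <- weightMatrix(buildCoexNetwork(x, networkBuildConfig(beta = 5, tau = 0)))
  expect_true(all(w5 <= w2 + 1e-15))
})

test_that("soft power selection picks the smallest passing exponent", {
  set.seed(33)
  # modular data: a rough power-law degree profile emerges under thresholding
  spec <- syntheticSpec(nGenes = 120, nModules = 6, moduleSize = 15,
                        nRewired = 0, seed = 5)
  x <- simulateExpression(spec)$exprs[[1]]
  cfg <- networkBuildConfig(powerGrid = 1:10, r2Target = 0.8, tau = 0.1)

  # independent grid scan with the fit recomputed from scratch
  R <- abs(stats::cor(t(x)))
  scan <- vapply(1:10, function(beta) {
    W <- R^beta; W[W < 0.1] <- 0; diag(W) <- 0
    deg <- rowSums(W > 0); deg <- deg[deg > 0]
    if (length(unique(deg)) < 3) return(NA_real_)
    bins <- cut(deg, 10)
    freq <- tapply(deg, bins, length); mid <- tapply(deg, bins, mean)
    keep <- !is.na(freq) & freq > 0
    if (sum(keep) < 3) return(NA_real_)
    summary(stats::lm(log10(freq[keep]) ~ log10(mid[keep])))$r.squared
  }, numeric(1))
  firstPass <- which(!is.na(scan) & scan >= 0.8)[1]

  if (!is.na(firstPass)) {
    expect_equal(selectSoftPower(x, cfg), firstPass)
  } else {
    expect_warning(beta <- selectSoftPower(x, cfg), "target")
    expect_equal(beta, which.max(scan))
  }

  # unreachable target: falls back to the best-fit exponent with a warning
  expect_warning(bestFit <- selectSoftPower(x,
    networkBuildConfig(powerGrid = 1:10, r2Target = 0.999999, tau = 0.1)),
    "target")
  expect_equal(bestFit, which.max(scan))

  # trivially passing target: the first candidate wins
  expect_equal(selectSoftPower(x,
    networkBuildConfig(powerGrid = 1:10, r2Target = 1e-6, tau = 0.1)), 1)
})

test_that("degenerate degree distributions fall back to the default power", {
  x <- rbind(gA = c(1, 2, 3, 4), gB = c(2, 4, 6, 8.1), gC = c(9, 2, 4, 1))
  expect_warning(beta <- selectSoftPower(x, networkBuildConfig(tau = 0)),
                 "degenerate")
  expect_equal(beta, 6)
})

test_that("network similarity is the edge-set Jaccard index", {
  ids <- c("A", "B", "C", "D")
  n1 <- mkNet(list(c("A", "B"), c("B", "C")), ids)
  n2 <- mkNet(list(c("B", "C"), c("C", "D")), ids)
  expect_equal(networkSimilarity(n1, n2), 1 / 3)
  expect_equal(networkSimilarity(n1, n1), 1)
  expect_equal(networkSimilarity(n1, n2), networkSimilarity(n2, n1))

  set.seed(9)
  WA <- randW(12); WB <- randW(12)
  nA <- CoexNetwork(WA); nB <- CoexNetwork(WB)
  ea <- oracleEdges(WA, rownames(WA)); eb <- oracleEdges(WB, rownames(WB))
  expect_equal(networkSimilarity(nA, nB),
               length(intersect(ea, eb)) / length(union(ea, eb)))

  empty <- CoexNetwork(matrix(0, 4, 4, dimnames = list(ids, ids)), ids)
  expect_warning(s <- networkSimilarity(empty, empty), "edgeless")
  expect_equal(s, 1)
  expect_error(networkSimilarity(n1, mkNet(list(c("A", "B")), c("A", "B"))),
               "same gene IDs")
})

test_that("CoexNetwork validity rejects malformed weight matrices", {
  ids <- c("a", "b", "c")
  W <- matrix(0, 3, 3, dimnames = list(ids, ids))
  W["a", "b"] <- 0.5             # asymmetric
  expect_error(CoexNetwork(W, ids), "symmetric")
  W["b", "a"] <- 0.5; diag(W) <- 0.2
  expect_error(CoexNetwork(W, ids), "diagonal")
  diag(W) <- 0; W["a", "c"] <- W["c", "a"] <- 1
  expect_error(CoexNetwork(W, ids), "\\[0, 1\\)")
})
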