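# Differential-coexpression scores: subnetwork extraction, star transform,
# DCGN-S and DCGN-I.

test_that("subnetwork extraction matches hand BFS on a path graph", {
  net <- mkNet(list(c("A", "B"), c("B", "C"), c("C", "D")),
               c("A", "B", "C", "D"))
  s1 <- extractSubnetwork(net, "A", 1)
  expect_setequal(nodeSet(s1), c("A", "B"))
  expect_setequal(edgeSet(s1), "A|B")
  s2 <- extractSubnetwork(net, "A", 2)
  expect_setequal(nodeSet(s2), c("A", "B", "C"))
  expect_setequal(edgeSet(s2), c("A|B", "B|C"))
  # isolated centre: singleton node set, empty edge set
  iso <- mkNet(list(c("A", "B")), c("A", "B", "Z"))
  sz <- extractSubnetwork(iso, "Z", 3)
  expect_identical(nodeSet(sz), "Z")
  expect_length(edgeSet(sz), 0)
  expect_error(extractSubnetwork(net, "missing", 1), "not in network")
})

test_that("subnetwork node sets equal the shortest-path-distance oracle", {
  set.seed(15)
  for (rep in 1:20) {
    W <- randW(15, p = 0.2)
    net <- CoexNetwork(W)
    for (center in sample(rownames(W), 4)) {
      for (k in 1:3) {
        sub <- extractSubnetwork(net, center, k)
        expect_setequal(nodeSet(sub), oracleBall(W, center, k))
        expect_setequal(edgeSet(sub), oracleEdges(W, nodeSet(sub)))
      }
    }
  }
})

test_that("topological dissimilarity follows hand set arithmetic", {
  ids <- c("A", "B", "C", "D", "E")
  nA <- mkNet(list(c("A", "B"), c("B", "C"), c("B", "D")), ids, phase = "t1")
  nB <- mkNet(list(c("A", "B"), c("B", "E")), ids, phase = "t2")
  expect_equal(dcgnS(nA, nB, "B", 1), 1 - 1 / 4)  # shared AB of 4 edges
  expect_equal(dcgnS(nA, nA, "B", 1), 0)
  # disjoint non-empty neighbourhood edge sets
  nC <- mkNet(list(c("B", "E"), c("B", "D")), ids, phase = "t3")
  nD <- mkNet(list(c("B", "A"), c("B", "C")), ids, phase = "t4")
  expect_equal(dcgnS(nC, nD, "B", 1), 1)
  # isolated in both phases: no evidence of change
  empty <- CoexNetwork(matrix(0, 5, 5, dimnames = list(ids, ids)), ids)
  expect_equal(dcgnS(empty, empty, "A", 2), 0)
  expect_error(dcgnS(nA, mkNet(list(c("A", "B")), c("A", "B")), "C", 1),
               "missing")
})

test_that("maximum least-step probability picks the best minimal-hop walk", {
  # i reaches j either via u (0.4 * 0.5) or via v (0.6 * 0.25)
  ids <- c("i", "u", "v", "j")
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W["i", "u"] <- W["u", "i"] <- 0.2
  W["i", "v"] <- W["v", "i"] <- 0.3
  W["u", "j"] <- W["j", "u"] <- 0.2
  W["v", "j"] <- W["j", "v"] <- 0.1
  net <- CoexNetwork(W, ids)
  M <- transitionMatrix(net)
  sub <- extractSubnetwork(net, "i", 2)
  expect_equal(maxLeastStepProb(sub, M, "u"), M["i", "u"])  # direct edge
  expect_equal(maxLeastStepProb(sub, M, "j"), 0.4 * 0.5)    # best 2-step walk
  expect_error(maxLeastStepProb(sub, M, "i"), "other than the center")
})

test_that("least-step probabilities equal exhaustive geodesic enumeration", {
  set.seed(29)
  done <- 0
  while (done < 60) {
    n <- sample(6:12, 1)
    W <- randW(n, p = 0.3)
    net <- CoexNetwork(W)
    M <- transitionMatrix(net)
    center <- sample(rownames(W), 1)
    k <- sample(1:3, 1)
    sub <- extractSubnetwork(net, center, k)
    partners <- setdiff(nodeSet(sub), center)
    if (!length(partners)) next
    done <- done + 1
    for (target in partners) {
      expect_equal(maxLeastStepProb(sub, M, target),
                   oracleMaxProb(weightMatrix(sub), M, center, target),
                   tolerance = 1e-12)
    }
  }
})

test_that("star transform degenerates correctly and inverts probabilities", {
  # single partner: probability 1, information exactly 0
  one <- mkNet(list(c("i", "u")), c("i", "u"))
  st1 <- starTransform(extractSubnetwork(one, "i", 1), transitionMatrix(one))
  expect_equal(unname(partnerProbs(st1)), 1)
  expect_equal(unname(partnerInfo(st1)), 0)

  # equal partners: both chains keep {1/2, 1/2}; I = -ln(1/2)/2 each
  two <- mkNet(list(c("i", "u"), c("i", "v")), c("i", "u", "v"),
               weights = c(0.4, 0.4))
  st2 <- starTransform(extractSubnetwork(two, "i", 1), transitionMatrix(two))
  expect_equal(unname(partnerProbs(st2)), c(0.5, 0.5))
  expect_equal(unname(partnerInfo(st2)), rep(log(2) / 2, 2))

  # unequal partners {0.8, 0.2} invert to {0.2, 0.8}
  skew <- mkNet(list(c("i", "u"), c("i", "v")), c("i", "u", "v"),
                weights = c(0.8, 0.2))
  st3 <- starTransform(extractSubnetwork(skew, "i", 1), transitionMatrix(skew))
  expect_equal(unname(partnerProbs(st3)[c("u", "v")]), c(0.2, 0.8))
  expect_equal(unname(partnerInfo(st3)[c("u", "v")]),
               c(-log(0.2) * 0.2, -log(0.8) * 0.8))

  # isolated centre: empty star
  iso <- mkNet(list(c("u", "v")), c("i", "u", "v"))
  st0 <- starTransform(extractSubnetwork(iso, "i", 1), transitionMatrix(iso))
  expect_length(partnerProbs(st0), 0)
})

test_that("star probabilities sum to 1, reverse order, and bound information", {
  set.seed(51)
  for (rep in 1:25) {
    W <- randW(10, p = 0.4)
    net <- CoexNetwork(W)
    M <- transitionMatrix(net)
    center <- sample(rownames(W)[rowSums(W) > 0], 1)
    st <- starTransform(extractSubnetwork(net, center, 2), M)
    if (length(partnerProbs(st)) < 2) next
    expect_equal(sum(st@pNorm), 1, tolerance = 1e-12)
    expect_equal(sum(st@pTrans), 1, tolerance = 1e-12)
    # inverse renormalisation reverses the partner ordering
    expect_equal(order(st@pNorm), rev(order(st@pTrans)))
    expect_true(all(partnerInfo(st) >= 0))
    expect_true(all(partnerInfo(st) <= 1 / exp(1) + 1e-12))  # max of -p ln p
  }
})

test_that("information variation handles degeneracies and hub collapse", {
  ids <- c("c", paste0("p", 1:2))
  WA <- matrix(0, 3, 3, dimnames = list(ids, ids))
  WA["c", 2:3] <- WA[2:3, "c"] <- 0.4
  netA <- CoexNetwork(WA, ids, "A")
  netEmpty <- CoexNetwork(matrix(0, 3, 3, dimnames = list(ids, ids)), ids, "B")
  # gene isolated in one phase, two equal neighbours in the other: ln 2
  expect_equal(dcgnI(netA, netEmpty, "c", 1), log(2))
  expect_equal(dcgnI(netEmpty, netA, "c", 1), log(2))  # symmetric
  expect_equal(dcgnI(netA, netA, "c", 1), 0)           # identical node sets
})

test_that("hub information grows logarithmically with collapsed degree", {
  vals <- vapply(c(2, 5, 10, 20), function(D) {
    ids <- c("c", sprintf("p%02d", seq_len(D)))
    W <- matrix(0, D + 1, D + 1, dimnames = list(ids, ids))
    W["c", -1] <- W[-1, "c"] <- 0.3
    dcgnI(CoexNetwork(W, ids, "A"),
          CoexNetwork(matrix(0, D + 1, D + 1, dimnames = list(ids, ids)),
                      ids, "B"),
          "c", 1)
  }, numeric(1))
  expect_equal(vals, log(c(2, 5, 10, 20)))   # exact closed form
  expect_true(all(diff(vals) > 0))           # non-decreasing in degree
})

test_that("both scores agree with brute-force oracles on random pairs", {
  set.seed(77)
  for (rep in 1:15) {
    WA <- randW(10, p = 0.3); WB <- randW(10, p = 0.3)
    nA <- CoexNetwork(WA, phaseLabel = "A")
    nB <- CoexNetwork(WB, phaseLabel = "B")
    MA <- transitionMatrix(nA); MB <- transitionMatrix(nB)
    for (gene in sample(rownames(WA), 4)) {
      for (k in 1:2) {
        expect_equal(dcgnS(nA, nB, gene, k), oracleDcgnS(WA, WB, gene, k))
        expect_equal(dcgnI(nA, nB, gene, k),
                     oracleDcgnI(WA, WB, MA, MB, gene, k), tolerance = 1e-10)
        # symmetry and range
        expect_equal(dcgnS(nA, nB, gene, k), dcgnS(nB, nA, gene, k))
        expect_equal(dcgnI(nA, nB, gene, k), dcgnI(nB, nA, gene, k))
        s <- dcgnS(nA, nB, gene, k)
        expect_true(s >= 0 && s <= 1)
        expect_gte(dcgnI(nA, nB, gene, k), 0)
      }
    }
  }
})

test_that("scoreAll produces one table per pair and matches per-gene calls", {
  set.seed(88)
  nets <- lapply(c("t1", "t2", "t3"), function(ph)
    CoexNetwork(randW(12, p = 0.3), phaseLabel = ph))
  for (metric in c("S", "I")) {
    tabs <- scoreAll(nets, metric = metric, k = 1)
    expect_length(tabs, 3)  # C(3, 2)
    expect_named(tabs, c("t1|t2", "t1|t3", "t2|t3"))
    fun <- if (metric == "S") dcgnS else dcgnI
    for (g in rownames(weightMatrix(nets[[1]]))[c(1, 5, 9)]) {
      expect_equal(tabs[["t1|t3"]]$value[tabs[["t1|t3"]]$gene == g],
                   fun(nets[[1]], nets[[3]], g, 1))
    }
  }
  # duplicated network: every score is zero
  dup <- scoreAll(list(nets[[1]], nets[[1]]), metric = "I", k = 2)
  expect_true(all(dup[[1]]$value == 0))
  # mismatched universes are rejected
  expect_error(scoreAll(list(nets[[1]], CoexNetwork(randW(5)))), "same gene IDs")
})
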