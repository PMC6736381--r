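fixA <- toyModel(c(2, 1), seed = 31)     # 3 states: brute force stays cheap
fix9a <- toyModel(c(3, 3, 2, 1), seed = 32)

test_that("marginal posteriors match brute-force enumeration", {
  tr <- randomTree(4, seed = 33, blRange = c(0.1, 0.5))
  sim <- simulateAlignment(tr, fixA$model, 5, seed = 34)
  aln <- sim$alignment
  aln@states[2, 3] <- 0L
  for (node in 5:7) {
    mr <- marginalReconstruct(tr, aln, fixA$model, nodes = node)
    for (s in 1:5)
      expect_equal(unname(mr$posterior[[1]][, s]),
                   bruteMarginal(tr, aln, fixA$model, node, s),
                   tolerance = 1e-10)
  }
  # posteriors are normalized
  mr <- marginalReconstruct(tr, aln, fixA$model)
  for (p in mr$posterior)
    expect_lt(max(abs(colSums(p) - 1)), 1e-10)
})

test_that("zero-length neighborhoods give point-mass posteriors", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0.3,d:0.3):0.1);")
  ab <- fixA$alphabet
  m <- matrix(c(2L, 2L, 1L, 3L), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  aln <- rotaAlignment(m, ab)
  node <- 4 + 2   # ancestor of the zero-length (a, b) cherry
  mr <- marginalReconstruct(tr, aln, fixA$model, nodes = node)
  expect_equal(unname(mr$posterior[[1]][2, 1]), 1, tolerance = 1e-12)
})

test_that("star-tree posterior follows the closed-form product", {
  # 3-leaf star, posterior at root ~ pi_k prod_i P_k,x_i(t_i)
  ab <- fixA$alphabet
  m <- fixA$model
  tr <- ape::read.tree(text = "(a:0.2,b:0.4,c:0.3);")
  aln <- rotaAlignment(matrix(c(1L, 1L, 2L), 3, 1,
                              dimnames = list(c("a", "b", "c"), NULL)), ab)
  post <- marginalReconstruct(tr, aln, m, nodes = 4)$posterior[[1]][, 1]
  Pa <- transitionMatrix(m, 0.2); Pb <- transitionMatrix(m, 0.4)
  Pc <- transitionMatrix(m, 0.3)
  expected <- stateFreqs(m) * Pa[, 1] * Pb[, 1] * Pc[, 2]
  expect_equal(unname(post), unname(expected / sum(expected)),
               tolerance = 1e-12)
})

test_that("joint reconstruction equals exhaustive argmax with its score", {
  tr <- randomTree(5, seed = 35, blRange = c(0.1, 0.5))
  sim <- simulateAlignment(tr, fixA$model, 6, seed = 36)
  aln <- sim$alignment
  aln@states[1, 5] <- -1L        # one masked tip character
  jr <- jointReconstruct(tr, aln, fixA$model)
  for (s in 1:6) {
    bj <- bruteJoint(tr, aln, fixA$model, s)
    expect_equal(jr$logProb[s], unname(bj$logProb), tolerance = 1e-10)
    expect_equal(unname(jr$states[6:9, s]), bj$states[6:9])
  }
  expect_equal(unname(jr$states[1, 5]),
               bruteJoint(tr, aln, fixA$model, 5)$states[1])
  # zero-length tree: all nodes copy the unanimous leaf state
  tr0 <- randomTree(4, seed = 37); tr0$edge.length[] <- 0
  aln0 <- rotaAlignment(matrix(2L, 4, 2, dimnames =
                                 list(paste0("t", 1:4), NULL)),
                        fixA$alphabet)
  jr0 <- jointReconstruct(tr0, aln0, fixA$model)
  expect_true(all(jr0$states == 2L))
})

test_that("joint score never exceeds the marginal site likelihood", {
  tr <- randomTree(4, seed = 38, blRange = c(0.1, 0.4))
  sim <- simulateAlignment(tr, fix9a$model, 20, seed = 39)
  jr <- jointReconstruct(tr, sim$alignment, fix9a$model)
  site <- pruningLoglik(tr, sim$alignment, fix9a$model)$siteLogLik
  expect_true(all(jr$logProb <= site + 1e-10))
})

test_that("root posterior is invariant to re-rooting", {
  tr <- randomTree(6, seed = 40, blRange = c(0.1, 0.4))
  sim <- simulateAlignment(tr, fix9a$model, 10, seed = 41)
  # compare the posterior at a fixed internal node across rootings
  ref <- marginalReconstruct(tr, sim$alignment, fix9a$model,
                             nodes = 8)$posterior[[1]]
  un <- ape::unroot(tr)
  clade <- ape::extract.clade(tr, 8)$tip.label
  rr <- ape::root(un, outgroup = setdiff(tr$tip.label, clade),
                  resolve.root = TRUE)
  mrca <- ape::getMRCA(rr, clade)
  post2 <- marginalReconstruct(rr, sim$alignment, fix9a$model,
                               nodes = mrca)$posterior[[1]]
  expect_equal(post2, ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("leave-leaves-out validates siblings and recovers easy cases", {
  tr <- ape::read.tree(text = "((a:0,b:0):0.1,(c:0.2,d:0.2):0.1);")
  ab <- fixA$alphabet
  m <- matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  aln <- rotaAlignment(m, ab)
  expect_error(leaveLeavesOut(tr, aln, c("a", "c"), fixA$model),
               "not siblings")
  expect_error(leaveLeavesOut(tr, aln, c("a", "zz"), fixA$model), "zz")
  for (alg in c("marginal", "joint")) {
    rec <- leaveLeavesOut(tr, aln, c("a", "b"), fixA$model, algorithm = alg)
    expect_equal(reconstructionAccuracy(rec, aln@states["a", ]), 100)
  }
  # sites unobserved in every remaining taxon come back as UNKNOWN
  m2 <- m; m2[c("c", "d"), 2] <- 0L
  aln2 <- rotaAlignment(m2, ab)
  rec2 <- leaveLeavesOut(tr, aln2, c("a", "b"), fixA$model)
  expect_equal(rec2[2], -1L)
})

test_that("accuracy is percent identity; masking can only help", {
  ab <- fix9a$alphabet
  x <- c(1L, 2L, 5L, 9L)
  expect_equal(reconstructionAccuracy(x, x), 100)
  expect_equal(reconstructionAccuracy(c(1L, 2L), c(2L, 1L)), 0)
  expect_error(reconstructionAccuracy(1L, c(1L, 2L)), "length")
  set.seed(42)
  for (r in 1:5) {
    a <- sample.int(9, 30, replace = TRUE)
    b <- sample.int(9, 30, replace = TRUE)
    expect_gte(reconstructionAccuracy(a, b, ab, mask = TRUE),
               reconstructionAccuracy(a, b))
  }
  # gaps excluded from the denominator
  expect_equal(reconstructionAccuracy(c(1L, -1L, 2L), c(1L, 5L, 0L)), 100)
})

test_that("reconstruction accuracy degrades with divergence", {
  m <- fix9a$model
  base <- randomTree(8, seed = 43)
  acc <- vapply(c(0.01, 1, 5), function(fac) {
    tr <- scaleTree(base, fac)
    sim <- simulateAlignment(tr, m, 150, seed = 44)
    jr <- jointReconstruct(tr, sim$alignment, m)
    truth <- siteStates(sim$internal)
    mean(vapply(rownames(truth), function(nd)
      reconstructionAccuracy(jr$states[nd, ], truth[nd, ]), numeric(1)))
  }, numeric(1))
  expect_gt(acc[1], 95)
  expect_true(all(diff(acc) < 0))
})
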