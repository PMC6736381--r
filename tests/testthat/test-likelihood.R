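fix9 <- toyModel(c(3, 3, 2, 1), seed = 11)

test_that("transition matrices are stochastic and form a semigroup", {
  m <- fix9$model
  expect_equal(transitionMatrix(m, 0), diag(9), ignore_attr = TRUE)
  for (t in c(0.05, 0.6, 3)) {
    P <- transitionMatrix(m, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_lt(max(abs(transitionMatrix(m, 0.3) %*% transitionMatrix(m, 0.45) -
                      transitionMatrix(m, 0.75))), 1e-9)
  expect_error(transitionMatrix(m, -1), "nonnegative")
  # symmetric two-state rate 1: P_11(t) = (1 + exp(-2t)) / 2
  ab2 <- toyAlphabet(c(1, 1))
  m2 <- exchToRateModel(matrix(c(0, 2, 2, 0), 2), c(0.5, 0.5), ab2,
                        rescale = "none")
  for (t in c(0.1, 1, 4))
    expect_equal(transitionMatrix(m2, t)[1, 1], (1 + exp(-2 * t)) / 2,
                 tolerance = 1e-12)
})

test_that("pruning matches closed forms on one- and two-taxon trees", {
  m <- fix9$model
  ab <- fix9$alphabet
  # single taxon, one site in state i: likelihood is pi_i
  tr1 <- list(edge = matrix(c(2L, 1L), 1), edge.length = 0.4,
              tip.label = "a", Nnode = 1L)
  class(tr1) <- "phylo"
  a1 <- rotaAlignment(matrix(3L, 1, 1, dimnames = list("a", NULL)), ab)
  expect_equal(pruningLoglik(tr1, a1, m)$logLik, log(stateFreqs(m)[3]),
               ignore_attr = TRUE)
  # two taxa: log sum_k pi_k P_ki(t1) P_kj(t2)
  tr2 <- ape::read.tree(text = "(a:0.2,b:0.35);")
  a2 <- rotaAlignment(matrix(c(2L, 7L), 2, 1, dimnames = list(c("a", "b"),
                                                              NULL)), ab)
  P1 <- transitionMatrix(m, 0.2); P2 <- transitionMatrix(m, 0.35)
  expect_equal(pruningLoglik(tr2, a2, m)$logLik,
               log(sum(stateFreqs(m) * P1[, 2] * P2[, 7])),
               tolerance = 1e-12)
  expect_error(pruningLoglik(tr2, a1, m), "taxon mismatch")
})

test_that("pruning equals brute-force enumeration, with and without gamma", {
  fix <- toyModel(c(2, 1), seed = 12)     # 3 states keep enumeration cheap
  tr <- randomTree(4, seed = 13, blRange = c(0.1, 0.6))
  sim <- simulateAlignment(tr, fix$model, 5, seed = 14)
  aln <- sim$alignment
  aln@states[1, 2] <- 0L; aln@states[3, 4] <- -1L    # inject ambiguity
  expect_equal(pruningLoglik(tr, aln, fix$model)$logLik,
               bruteLoglik(tr, aln, fix$model), tolerance = 1e-8)
  g <- discreteGamma(0.4, 4)
  expect_equal(pruningLoglik(tr, aln, fix$model, g)$logLik,
               bruteLoglik(tr, aln, fix$model, g), tolerance = 1e-8)
  # a 9-state fixture on a 5-taxon tree against the same oracle
  tr5 <- randomTree(5, seed = 15, blRange = c(0.05, 0.4))
  sim5 <- simulateAlignment(tr5, fix9$model, 3, seed = 16)
  expect_equal(pruningLoglik(tr5, sim5$alignment, fix9$model)$logLik,
               bruteLoglik(tr5, sim5$alignment, fix9$model),
               tolerance = 1e-8)
})

test_that("log-likelihood is invariant to root placement", {
  tr <- randomTree(6, seed = 17, blRange = c(0.05, 0.5))
  sim <- simulateAlignment(tr, fix9$model, 40, seed = 18)
  ref <- pruningLoglik(tr, sim$alignment, fix9$model)$logLik
  un <- ape::unroot(tr)
  expect_equal(pruningLoglik(un, sim$alignment, fix9$model)$logLik, ref,
               tolerance = 1e-9)
  for (og in c("t2", "t5")) {
    rr <- ape::root(un, outgroup = og, resolve.root = TRUE)
    expect_equal(pruningLoglik(rr, sim$alignment, fix9$model)$logLik, ref,
                 tolerance = 1e-9)
  }
})

test_that("gamma discretization matches quadrature and its limits", {
  for (alpha in c(0.2, 0.5, 2)) {
    g <- discreteGamma(alpha, 4)
    expect_equal(g@rates, quadGammaRates(alpha, 4), tolerance = 1e-6)
    expect_true(all(diff(g@rates) > 0))          # strictly increasing
    expect_equal(mean(g@rates), 1, tolerance = 1e-12)
  }
  expect_true(all(abs(discreteGamma(1e7, 4)@rates - 1) < 1e-3))
  expect_error(discreteGamma(0, 4), "positive")
})

test_that("branch lengths are recovered and optimization is stable", {
  m <- fix9$model
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  sim <- simulateAlignment(tr, m, 4000, seed = 19)
  fit <- optimizeBranchLengths(tr, sim$alignment, m)
  that <- sum(fit$tree$edge.length)
  f <- function(t) {
    tt <- tr; tt$edge.length <- c(t / 2, t / 2)
    pruningLoglik(tt, sim$alignment, m)$logLik
  }
  se <- numericSE(f, that, 1e-3)
  expect_lt(abs(that - 0.3), 3 * se)
  # optimizing again changes the log-likelihood below tolerance
  fit2 <- optimizeBranchLengths(fit$tree, sim$alignment, m)
  expect_lt(abs(fit2$logLik - fit$logLik), 1e-5)
  # the optimum is a local maximum in each branch
  eps <- 0.02
  expect_gt(fit$logLik, f(that + eps))
  expect_gt(fit$logLik, f(that - eps))
  # identical sequences drive branch lengths to the lower bound
  same <- rotaAlignment(matrix(rep(c(1L, 4L, 6L), each = 2), 2,
                               dimnames = list(c("a", "b"), NULL)),
                        fix9$alphabet)
  fit0 <- optimizeBranchLengths(tr, same, m)
  expect_true(all(fit0$tree$edge.length <= 1e-5))
})

test_that("gamma shape and +F frequencies are recovered from simulations", {
  m <- fix9$model
  tr <- randomTree(4, seed = 20, blRange = c(0.1, 0.3))
  g <- discreteGamma(0.5, 4)
  sim <- simulateAlignment(tr, m, 2000, seed = 21, rates = g)
  oa <- optimizeAlpha(tr, sim$alignment, m)
  se <- numericSE(function(a)
    pruningLoglik(tr, sim$alignment, m, discreteGamma(a, 4))$logLik,
    oa$alpha, 1e-3)
  expect_lt(abs(oa$alpha - 0.5), 3 * se)
  # data without rate variation pushes alpha toward the homogeneous limit:
  # the estimate is large and gamma adds nothing over the plain model
  simFlat <- simulateAlignment(tr, m, 400, seed = 22)
  oaFlat <- optimizeAlpha(tr, simFlat$alignment, m, interval = c(0.02, 50))
  expect_gt(oaFlat$alpha, 2)
  gain <- oaFlat$logLik - pruningLoglik(tr, simFlat$alignment, m)$logLik
  expect_lt(gain / 400, 0.01)    # negligible per-site improvement
  # +F: frequencies used for simulation are recovered
  set.seed(23)
  pi0 <- stateFreqs(m) * stats::runif(9, 0.6, 1.6)
  pi0 <- pi0 / sum(pi0)
  mf <- exchToRateModel(exchangeabilities(m), pi0, fix9$alphabet)
  simF <- simulateAlignment(tr, mf, 4000, seed = 24)
  of <- optimizeFrequencies(tr, simF$alignment, m)
  expect_lt(max(abs(of$freqs - pi0)), 0.03)
  expect_gte(of$logLik + 1e-6,
             pruningLoglik(tr, simF$alignment, m)$logLik)
})

test_that("branch-score distance enumerates bipartitions correctly", {
  t1 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.4):0.15);")
  expect_equal(euclideanTreeDistance(t1, t1), 0)
  # same topology, one pendant branch perturbed by delta
  t2 <- t1
  ea <- which(t2$edge[, 2] == which(t2$tip.label == "a"))
  t2$edge.length[ea] <- t2$edge.length[ea] + 0.25
  expect_equal(euclideanTreeDistance(t1, t2), 0.25)
  # conflicting central bipartition: each tree's internal split (lengths
  # 0.05+0.15 and 0.08+0.12 after unrooting) is missing from the other
  t3 <- ape::read.tree(text = "((a:0.1,c:0.3):0.08,(b:0.2,d:0.4):0.12);")
  expect_equal(euclideanTreeDistance(t1, t3), sqrt(0.2^2 + 0.2^2))
  # matches the field-standard implementation on random trees
  skip_if_not_installed("phangorn")
  for (s in 1:3) {
    x <- randomTree(7, seed = s); y <- randomTree(7, seed = s + 50)
    expect_equal(euclideanTreeDistance(x, y), phangorn::KF.dist(x, y),
                 tolerance = 1e-12)
  }
  expect_error(euclideanTreeDistance(t1, randomTree(5)), "leaf sets")
})
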