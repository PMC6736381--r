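fixU <- toyModel(c(3, 3, 2, 1), seed = 21)
lump20 <- countsToRateModel(fixU$counts20, fixU$alphabet20, scaling = "rotamer")
expU <- expandUniform(fixU$counts20, fixU$alphabet)

test_that("AIC arithmetic and ordering", {
  expect_equal(aic(-100, 5), 210)
  expect_equal(aic(0, 0), 0)
  expect_lt(aic(-10, 3), aic(-20, 3))
  expect_error(aic(-10, -1), "nonnegative")
})

test_that("state-space correction sums per-character frequency ratios", {
  ab <- fixU$alphabet
  mult <- rotamerMultiplicity(ab)
  pi20 <- stateFreqs(lump20)
  pi55u <- pi20[maskIndex(ab)] / mult[maskIndex(ab)]   # uniform expansion
  # six non-gap characters from 3-configuration pseudo-residues
  st <- which(aminoAcids(ab) == aaLevels(ab)[1])[c(1, 2, 3, 1, 2, 3)]
  m <- matrix(st, 2, 3, dimnames = list(c("x", "y"), NULL))
  aln <- rotaAlignment(m, ab)
  corr <- stateCorrectedLoglik(0, aln, pi55u, pi20)
  expect_equal(corr, 6 * log(1 / 3), tolerance = 1e-12)
  # all-gap alignment contributes nothing
  gaps <- rotaAlignment(matrix(0L, 2, 3, dimnames = list(c("x", "y"), NULL)),
                        ab)
  expect_equal(stateCorrectedLoglik(-12.3, gaps, pi55u, pi20), -12.3)
  # appending all-gap columns never changes the correction
  aln2 <- rotaAlignment(cbind(m, matrix(0L, 2, 4)), ab)
  expect_equal(stateCorrectedLoglik(0, aln2, pi55u, pi20), corr)
  expect_error(stateCorrectedLoglik(0, aln, pi55u * 0, pi20), "zero")
})

test_that("uniform expansion reproduces its defining rate identities", {
  e <- expandUniform(fixU$counts20, fixU$alphabet, scaling = "none")
  l <- countsToRateModel(fixU$counts20, fixU$alphabet20, scaling = "none")
  map <- maskIndex(fixU$alphabet)
  mult <- rotamerMultiplicity(fixU$alphabet)
  Q55 <- rateMatrix(e); Q20 <- rateMatrix(l)
  for (i in seq_along(map)) for (j in seq_along(map)) {
    if (map[i] != map[j])
      expect_equal(unname(Q55[i, j]),
                   unname(Q20[map[i], map[j]] / mult[map[j]]),
                   tolerance = 1e-12)
  }
  # masked equilibrium frequencies equal the amino-acid frequencies
  piAgg <- tapply(stateFreqs(e), map, sum)
  expect_equal(unname(as.numeric(piAgg)), unname(stateFreqs(l)),
               tolerance = 1e-12)
  expect_equal(unname(stateFreqs(e)),
               unname(stateFreqs(l)[map] / mult[map]), tolerance = 1e-12)
})

test_that("the expanded chain lumps exactly onto the amino-acid chain", {
  map <- maskIndex(fixU$alphabet)
  for (t in c(0.01, 0.4, 2, 10)) {
    P55 <- transitionMatrix(expU, t)
    P20 <- transitionMatrix(lump20, t)
    agg <- t(rowsum(t(P55), factor(map)))
    expect_lt(max(abs(agg - P20[map, ])), 1e-10)
  }
})

test_that("KL information loss behaves as an information measure", {
  m55 <- fixU$model
  # zero at t = 0 for every state
  expect_true(all(abs(vapply(seq_len(9), function(s)
    klDivergence(m55, lump20, s, 0), numeric(1))) < 1e-10))
  prof <- klProfile(m55, lump20,
                    tGrid = exp(seq(log(0.01), log(8), length.out = 40)))
  expect_true(all(prof$bits >= -1e-12))
  # normalization shares amino-acid equilibria, so loss vanishes at large t
  expect_lt(klProfile(m55, lump20, tGrid = 1000)$bits, 1e-6)
  # a uniform expansion loses nothing at any t (lumpability)
  profU <- klProfile(expU, lump20,
                     tGrid = exp(seq(log(0.01), log(5), length.out = 25)))
  expect_lt(max(abs(profU$bits)), 1e-10)
  # the estimated model does lose information relative to its lumping
  expect_gt(max(prof$bits), 1e-4)
})

test_that("frequency-weighted expansion respects its construction", {
  pi55 <- stateFreqs(fixU$model)
  e <- expandByFreq(fixU$counts20, pi55, fixU$alphabet, scaling = "none")
  # submatrix sums proportional to n_AA' x the pi-products
  map <- maskIndex(fixU$alphabet)
  Nbar <- fixU$counts20[map, map] * outer(pi55, pi55)
  agg <- lumpCounts(Nbar, fixU$alphabet)
  lev <- aaLevels(fixU$alphabet)
  piA <- tapply(pi55, map, sum)
  expect_equal(unname(agg),
               unname(fixU$counts20 * outer(as.numeric(piA),
                                            as.numeric(piA))),
               tolerance = 1e-12)
  # reversible, with stationary frequencies proportional to row sums
  expect_lt(max(abs(stateFreqs(e) %*% rateMatrix(e))), 1e-12)
  db <- stateFreqs(e) * rateMatrix(e)
  expect_lt(max(abs(db - t(db))), 1e-12)
  # counts reconstructed from a model push back through the pipeline to
  # the same model (frequencies and scaled rates recovered exactly)
  N <- countsFromExchangeabilities(exchangeabilities(lump20),
                                   stateFreqs(lump20))
  expect_equal(max(abs(N - t(N))), 0)
  m2 <- countsToRateModel(N, fixU$alphabet20, scaling = "rotamer")
  expect_lt(max(abs(stateFreqs(m2) - stateFreqs(lump20))), 1e-12)
  expect_lt(max(abs(rateMatrix(m2) - rateMatrix(lump20))), 1e-12)
})

test_that("model comparison ranks the generating model first", {
  tr <- randomTree(8, seed = 22, blRange = c(0.05, 0.4))
  sim <- simulateAlignment(tr, fixU$model, 800, seed = 23)
  rep <- compareModels(sim$alignment, tr,
                       list(generating = fixU$model, lumped = lump20,
                            uniform = expU))
  expect_equal(rep$model[which.min(rep$AIC)], "generating")
  expect_equal(rep$k, rep_len(length(tr$edge.length), 3))
  # corrected and raw agree for expanded-space models
  expect_equal(rep$rawLogLik[1], rep$correctedLogLik[1])
  expect_lt(rep$correctedLogLik[2], rep$rawLogLik[2])
})
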