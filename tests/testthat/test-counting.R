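test_that("neighbor joining recovers an additive tree exactly", {
  # additive distances for ((a:0.1,b:0.2):0.1,(c:0.15,d:0.25))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 0.3; d["a", "c"] <- 0.35; d["a", "d"] <- 0.45
  d["b", "c"] <- 0.45; d["b", "d"] <- 0.55; d["c", "d"] <- 0.4
  d <- d + t(d)
  tr <- njTree(d)
  # the tree's path-length distances reproduce the input (additivity)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-12)
  # ab|cd bipartition present
  expect_equal(euclideanTreeDistance(tr, tr), 0)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
  dn <- d; dn[1, 2] <- NA; dn[2, 1] <- NA
  expect_error(njTree(dn), "finite")
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  cp <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]
  expect_equal(cp, d, tolerance = 1e-12)  # 3 points are always additive
  # zero distances give a zero-length tree
  d0 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(sum(njTree(d0)$edge.length), 0)
})

test_that("circular tour visits each leaf in exactly two comparisons", {
  for (n in c(2, 4, 7, 12)) {
    tr <- randomTree(n, seed = n)
    ord <- circularLeafOrder(tr)
    expect_setequal(ord, tr$tip.label)
    pairs <- cbind(ord, c(ord[-1], ord[1]))
    key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    expect_equal(nrow(pairs), if (n == 2) 1L else n)
    if (n > 2)
      expect_true(all(table(c(pairs)) == 2))
  }
})

test_that("pair counting respects identity threshold and symmetry", {
  # 1 difference in 4 sites: identity 0.75 is counted (only <75% is omitted)
  inc <- pairCounts(c(1L, 2L, 3L, 1L), c(1L, 2L, 3L, 2L), 3)
  expect_equal(attr(inc, "identity"), 0.75)
  expect_equal(inc[1, 2], 1); expect_equal(inc[2, 1], 1)
  expect_equal(diag(inc), c(2, 2, 2))           # conserved sites add 2
  expect_equal(sum(inc), 8)                      # 4 sites x 2 orderings
  # 2 differences in 4: identity 0.5 -> skipped
  expect_null(pairCounts(c(1L, 1L, 1L, 1L), c(1L, 1L, 2L, 2L), 3))
  # identical sequences: diagonal only
  inc <- pairCounts(c(2L, 2L, 3L), c(2L, 2L, 3L), 3)
  expect_equal(sum(inc) - sum(diag(inc)), 0)
  # gap/unknown sites are ignored before the identity computation
  inc <- pairCounts(c(1L, 0L, 2L), c(1L, 2L, -1L), 3)
  expect_equal(sum(inc), 2)                      # one comparable site
  expect_error(pairCounts(c(1L, 2L), c(1L,  2L, 3L), 3), "length")
})

test_that("family accumulation is symmetric, order-invariant, near truth", {
  fix <- toyModel(c(3, 2, 1), seed = 3)
  tr <- randomTree(6, seed = 7, blRange = c(0.005, 0.03))
  fam <- plantedFamily(tr, fix$model, 300, seed = 8)
  cnt <- accumulateFamily(fam$alignment)
  expect_equal(max(abs(cnt - t(cnt))), 0)
  expect_equal(attr(cnt, "nPairs"), 6L)
  # two-taxon alignment equals the single pair count
  two <- rotaAlignment(fam$alignment@states[1:2, ], fix$alphabet)
  expect_equal(unname(accumulateFamily(two)),
               unname(pairCounts(two@states[1, ], two@states[2, ], 6)),
               ignore_attr = TRUE)
  # invariance to input taxon order
  set.seed(1)
  perm <- sample(6)
  cnt2 <- accumulateFamily(rotaAlignment(fam$alignment@states[perm, ],
                                         fix$alphabet))
  expect_equal(unname(cnt), unname(cnt2))
  # at low divergence the tour tallies bracket the planted branch tallies:
  # each planted event is seen in one or two of a leaf's comparisons
  offTour <- sum(cnt) - sum(diag(cnt))
  offTrue <- sum(fam$trueCounts) - sum(diag(fam$trueCounts))
  expect_gt(offTour, 0)
  expect_lte(offTour, 2 * offTrue)
  expect_gte(offTour, 0.5 * offTrue)
})

test_that("normalization enforces amino-acid marginals and symmetry", {
  fix <- toyModel(c(3, 2, 1), seed = 9)
  # arithmetic: submatrix (2,3,0,0,..) summing 5 rescaled to n20 = 10
  ab <- toyAlphabet(c(2, 1))
  n55 <- matrix(0, 3, 3)
  n55[1, 2] <- 1; n55[2, 1] <- 1; n55[1, 1] <- 3; n55[2, 2] <- 0
  n55[3, 3] <- 4
  n20 <- matrix(c(10, 0, 0, 4), 2, 2)   # A/A submatrix sums 5, target 10
  nh <- normalizeCounts(n55, n20, ab)
  expect_equal(nh[1, 2], 1 * 10 / 5)
  expect_equal(nh[1, 1], 3 * 10 / 5)
  expect_equal(nh[3, 3], 4)
  # fixed point: counts already consistent with their own lumping
  lump <- lumpCounts(fix$counts, fix$alphabet)
  expect_equal(normalizeCounts(fix$counts, lump, fix$alphabet), fix$counts,
               tolerance = 1e-12)
  # random fixture: every submatrix sums to the target within 1e-9
  set.seed(10)
  tgt <- lump * matrix(stats::runif(16, 0.5, 2), 4)[seq_len(nrow(lump)),
                                                    seq_len(ncol(lump))]
  tgt <- (tgt + t(tgt)) / 2
  nh2 <- normalizeCounts(fix$counts, tgt, fix$alphabet)
  expect_lt(max(abs(lumpCounts(nh2, fix$alphabet) - tgt)), 1e-9)
  expect_equal(max(abs(nh2 - t(nh2))), 0)
  # amino-acid marginal frequencies follow the 20-state counts
  pi20 <- rowSums(tgt) / sum(tgt)
  pi55agg <- tapply(rowSums(nh2) / sum(nh2),
                    factor(aminoAcids(fix$alphabet),
                           levels = aaLevels(fix$alphabet)), sum)
  expect_equal(unname(as.numeric(pi55agg)), unname(pi20), tolerance = 1e-12)
})

test_that("zero submatrices error by default, spread under a pseudocount", {
  ab <- toyAlphabet(c(2, 1))
  n55 <- diag(c(2, 2, 4))
  n20 <- matrix(c(4, 3, 3, 4), 2, 2)      # A/B exchange seen only in 20-state
  expect_error(normalizeCounts(n55, n20, ab), "pseudocount")
  nh <- normalizeCounts(n55, n20, ab, pseudocount = 0.5)
  expect_equal(sum(nh[1:2, 3]), 3)
  expect_equal(nh[1, 3], nh[2, 3])        # uniform spread
})
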