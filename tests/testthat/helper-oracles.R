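# Independent oracles: brute-force likelihood/posterior/joint computations
# by exhaustive enumeration over internal-node states, geometric helpers,
# and a quadrature oracle for the gamma discretization. These deliberately
# avoid the package's pruning/message-passing code paths.

bruteSiteLik <- function(tree, tipStates, model, site, Ps) {
  n <- length(model@pi)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internals <- (ntip + 1L):nn
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internals))))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    asg <- integer(nn); asg[internals] <- combos[r, ]
    pr <- model@pi[asg[ntip + 1L]]
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      if (ch <= ntip) {
        x <- tipStates[ch, site]
        pr <- pr * (if (x > 0) Ps[[k]][asg[p], x] else 1)
      } else pr <- pr * Ps[[k]][asg[p], asg[ch]]
    }
    tot <- tot + pr
  }
  tot
}

bruteLoglik <- function(tree, aln, model, rates = NULL) {
  tipStates <- rotasub:::.alignTipsToTree(tree, aln)
  rv <- if (is.null(rates)) 1 else rates@rates
  sitel <- matrix(0, length(rv), ncol(tipStates))
  for (ci in seq_along(rv)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
      transitionMatrix(model, tree$edge.length[k] * rv[ci]))
    for (s in seq_len(ncol(tipStates)))
      sitel[ci, s] <- bruteSiteLik(tree, tipStates, model, s, Ps)
  }
  sum(log(colMeans(sitel)))
}

bruteMarginal <- function(tree, aln, model, node, site) {
  tipStates <- rotasub:::.alignTipsToTree(tree, aln)
  n <- length(model@pi)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
    transitionMatrix(model, tree$edge.length[k]))
  internals <- (ntip + 1L):nn
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internals))))
  post <- numeric(n)
  for (r in seq_len(nrow(combos))) {
    asg <- integer(nn); asg[internals] <- combos[r, ]
    pr <- model@pi[asg[ntip + 1L]]
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      if (ch <= ntip) {
        x <- tipStates[ch, site]
        pr <- pr * (if (x > 0) Ps[[k]][asg[p], x] else 1)
      } else pr <- pr * Ps[[k]][asg[p], asg[ch]]
    }
    post[asg[node]] <- post[asg[node]] + pr
  }
  post / sum(post)
}

bruteJoint <- function(tree, aln, model, site) {
  tipStates <- rotasub:::.alignTipsToTree(tree, aln)
  n <- length(model@pi)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
    transitionMatrix(model, tree$edge.length[k]))
  ambTips <- which(tipStates[, site] <= 0L)
  vars <- c((ntip + 1L):nn, ambTips)
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), length(vars))))
  best <- -Inf; bestAsg <- NULL
  for (r in seq_len(nrow(combos))) {
    asg <- integer(nn); asg[vars] <- combos[r, ]
    obs <- setdiff(seq_len(ntip), ambTips)
    asg[obs] <- tipStates[obs, site]
    pr <- model@pi[asg[ntip + 1L]]
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * Ps[[k]][asg[tree$edge[k, 1]], asg[tree$edge[k, 2]]]
    if (pr > best) { best <- pr; bestAsg <- asg }
  }
  list(logProb = log(best), states = bestAsg)
}

# rotate point p about the axis through `origin` with direction `axis`
rotateAbout <- function(p, axis, angleDeg, origin) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  v <- p - origin
  v * cos(th) +
    c(a[2]*v[3] - a[3]*v[2], a[3]*v[1] - a[1]*v[3], a[1]*v[2] - a[2]*v[1]) *
      sin(th) + a * sum(a * v) * (1 - cos(th)) + origin
}

# random rigid motion applied to a list of points
rigidMotion <- function(points, seed) {
  set.seed(seed)
  ang <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1,0,0), c(0,cos(ang[1]),-sin(ang[1])), c(0,sin(ang[1]),cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]),0,sin(ang[2])), c(0,1,0), c(-sin(ang[2]),0,cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]),-sin(ang[3]),0), c(sin(ang[3]),cos(ang[3]),0), c(0,0,1))
  R <- Rx %*% Ry %*% Rz
  tr <- stats::runif(3, -5, 5)
  lapply(points, function(p) as.numeric(R %*% p + tr))
}

# gamma bin means by numerical integration
quadGammaRates <- function(alpha, k) {
  r <- vapply(seq_len(k), function(i) {
    lo <- stats::qgamma((i - 1) / k, alpha, rate = alpha)
    hi <- stats::qgamma(i / k, alpha, rate = alpha)
    stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                     lo, hi, rel.tol = 1e-10)$value * k
  }, numeric(1))
  r / mean(r)
}

# curvature-based standard error of a univariate ML estimate
numericSE <- function(f, xhat, h) {
  d2 <- (f(xhat + h) - 2 * f(xhat) + f(xhat - h)) / h^2
  1 / sqrt(-d2)
}
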