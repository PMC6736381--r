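# Felsenstein pruning over arbitrary state spaces, with discrete-gamma rate
# heterogeneity, coordinate-wise branch-length optimization, ML shape and
# frequency estimation, and the branch-score tree distance.
#
# Transition probabilities use the symmetric eigendecomposition available
# for reversible models: with D = diag(sqrt(pi)), B = D Q D^-1 is symmetric,
# so P(t) = D^-1 V exp(Lt) V' D with B = V L V'. The decomposition is done
# once per model and reused across branches and rate categories.

.decomposeModel <- function(model) {
  sp <- sqrt(model@pi)
  B <- (sp * model@Q) %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = diag(1 / sp) %*% e$vectors, Ut = t(e$vectors) %*% diag(sp),
       lambda = e$values)
}

.pmatFromDecomp <- function(dec, t) {
  if (t == 0) return(diag(length(dec$lambda)))
  P <- dec$U %*% (exp(dec$lambda * t) * dec$Ut)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' @param model a \linkS4class{RateModel}.
#' @param t nonnegative time (branch length in the model's scaling units).
#' @return row-stochastic matrix of transition probabilities.
#' @examples
#' fix <- toyModel(c(2, 1), seed = 1)
#' transitionMatrix(fix$model, 0.5)
#' @export
transitionMatrix <- function(model, t) {
  if (t < 0) stop("t must be nonnegative")
  P <- .pmatFromDecomp(.decomposeModel(model), t)
  dimnames(P) <- dimnames(model@Q)
  P
}

#' Discretized gamma rate categories (mean method)
#'
#' K equal-probability categories of a Gamma(alpha, alpha) distribution,
#' each represented by its within-bin mean, so category rates average 1.
#'
#' @param alpha shape parameter (> 0).
#' @param k number of categories (default 4).
#' @return a \linkS4class{GammaRates}.
#' @export
discreteGamma <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  ib <- stats::pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  rates <- k * diff(ib)
  rates <- rates / mean(rates)
  new("GammaRates", alpha = alpha, k = k, rates = rates)
}

.alignTipsToTree <- function(tree, aln) {
  lab <- tree$tip.label
  tx <- rownames(aln@states)
  miss <- setdiff(lab, tx); extra <- setdiff(tx, lab)
  if (length(miss) || length(extra))
    stop("taxon mismatch between tree and alignment; missing from alignment: ",
         paste(miss, collapse = ", "), "; absent from tree: ",
         paste(extra, collapse = ", "))
  aln@states[match(lab, tx), , drop = FALSE]
}

.tipMessage <- function(P, st, nStates, nSitesN) {
  M <- matrix(1, nStates, nSitesN)
  ok <- st > 0L
  if (any(ok)) M[, ok] <- P[, st[ok], drop = FALSE]
  M
}

# One post-order pass for one rate category; returns root partials and the
# per-site log-scaling accumulated below each node.
.pruneOnce <- function(po, tipStates, dec, rate, nStates) {
  nn <- max(po$edge)
  ntip <- nrow(tipStates)
  nSitesN <- ncol(tipStates)
  partial <- vector("list", nn)
  plog <- vector("list", nn)
  E <- po$edge; el <- po$edge.length
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    P <- .pmatFromDecomp(dec, el[k] * rate)
    if (ch <= ntip) {
      msg <- .tipMessage(P, tipStates[ch, ], nStates, nSitesN)
      mlog <- 0
    } else {
      part <- partial[[ch]]
      mx <- apply(part, 2, max)
      mx[mx <= 0] <- 1
      part <- sweep(part, 2, mx, "/")
      mlog <- plog[[ch]] + log(mx)
      msg <- P %*% part
    }
    if (is.null(partial[[p]])) {
      partial[[p]] <- msg
      plog[[p]] <- mlog
    } else {
      partial[[p]] <- partial[[p]] * msg
      plog[[p]] <- plog[[p]] + mlog
    }
  }
  root <- ntip + 1L
  list(partial = partial[[root]], plog = plog[[root]])
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Computes the log-likelihood of an alignment on a tree under a reversible
#' model, optionally with discrete-gamma rate heterogeneity (per-site
#' likelihoods are equal-weight averages over categories). Gaps and unknown
#' states are treated as total ambiguity. Per-node rescaling keeps the
#' computation stable on large trees.
#'
#' @param tree an \pkg{ape} \code{phylo} tree with branch lengths in the
#'   model's time units; polytomies (including unrooted trees stored with a
#'   basal trifurcation) are handled.
#' @param aln a \linkS4class{RotaAlignment} whose taxa match the tree's tips.
#' @param model a \linkS4class{RateModel} on the alignment's alphabet.
#' @param rates optional \linkS4class{GammaRates}.
#' @return list with \code{logLik} (total) and \code{siteLogLik}.
#' @export
pruningLoglik <- function(tree, aln, model, rates = NULL) {
  if (!identical(aln@alphabet@labels, model@alphabet@labels))
    stop("alignment and model use different state spaces")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tipStates <- .alignTipsToTree(tree, aln)
  po <- stats::reorder(tree, "postorder")
  dec <- .decomposeModel(model)
  n <- length(model@pi)
  rv <- if (is.null(rates)) 1 else rates@rates
  siteCat <- matrix(NA_real_, length(rv), ncol(tipStates))
  for (ci in seq_along(rv)) {
    pr <- .pruneOnce(po, tipStates, dec, rv[ci], n)
    lik <- colSums(model@pi * pr$partial)
    siteCat[ci, ] <- log(lik) + pr$plog
  }
  if (length(rv) == 1L) site <- siteCat[1, ]
  else {
    mx <- apply(siteCat, 2, max)
    site <- mx + log(colMeans(exp(sweep(siteCat, 2, mx, "-"))))
  }
  list(logLik = sum(site), siteLogLik = site)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise univariate optimization of each branch in turn, repeated
#' until the total log-likelihood improves by less than \code{tol} or
#' \code{maxRounds} is reached.
#'
#' @inheritParams pruningLoglik
#' @param tol convergence tolerance on the log-likelihood.
#' @param maxRounds maximum sweeps over all branches.
#' @param bounds branch-length search interval.
#' @return list with the updated \code{tree}, final \code{logLik}, and
#'   \code{converged} flag.
#' @export
optimizeBranchLengths <- function(tree, aln, model, rates = NULL, tol = 1e-6,
                                  maxRounds = 50L, bounds = c(1e-6, 100)) {
  cur <- pruningLoglik(tree, aln, model, rates)$logLik
  converged <- FALSE
  for (round in seq_len(maxRounds)) {
    prev <- cur
    for (e in seq_along(tree$edge.length)) {
      f <- function(b) {
        tr <- tree
        tr$edge.length[e] <- b
        pruningLoglik(tr, aln, model, rates)$logLik
      }
      opt <- stats::optimize(f, interval = bounds, maximum = TRUE, tol = 1e-8)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged && maxRounds > 1L)
    warning("branch-length optimization did not fully converge; ",
            "returning best-so-far")
  list(tree = tree, logLik = cur, converged = converged)
}

#' ML estimate of the gamma shape parameter
#'
#' @inheritParams pruningLoglik
#' @param k number of gamma categories.
#' @param interval search bounds for alpha.
#' @return list with \code{alpha}, \code{rates} and \code{logLik}.
#' @export
optimizeAlpha <- function(tree, aln, model, k = 4L, interval = c(0.02, 100)) {
  f <- function(la)
    pruningLoglik(tree, aln, model, discreteGamma(exp(la), k))$logLik
  opt <- stats::optimize(f, interval = log(interval), maximum = TRUE,
                         tol = 1e-6)
  alpha <- exp(opt$maximum)
  list(alpha = alpha, rates = discreteGamma(alpha, k), logLik = opt$objective)
}

#' ML estimation of equilibrium frequencies (+F)
#'
#' Maximizes the likelihood over the frequency simplex, rebuilding the rate
#' matrix from the model's exchangeabilities at each step (the +F
#' mechanism). Frequencies are parametrized as log-ratios to the last state.
#'
#' @inheritParams pruningLoglik
#' @param maxit optimizer iteration cap.
#' @return list with the refitted \code{model}, \code{freqs} and
#'   \code{logLik}.
#' @export
optimizeFrequencies <- function(tree, aln, model, rates = NULL, maxit = 500L) {
  n <- length(model@pi)
  S <- model@S
  ab <- model@alphabet
  sc <- model@scaling
  obs <- tabulate(aln@states[aln@states > 0L], nbins = n) + 0.5
  start <- log(obs / obs[n])[-n]
  f <- function(eta) {
    if (any(abs(eta) > 30)) return(1e10)   # reject degenerate proposals
    p <- exp(c(eta, 0)); p <- p / sum(p)
    tryCatch({
      m <- exchToRateModel(S, p, ab, rescale = sc)
      -pruningLoglik(tree, aln, m, rates)$logLik
    }, error = function(e) 1e10)
  }
  opt <- stats::optim(start, f, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  p <- exp(c(opt$par, 0)); p <- p / sum(p)
  names(p) <- ab@labels
  m <- exchToRateModel(S, p, ab, rescale = sc)
  list(model = m, freqs = p, logLik = -opt$value)
}

# canonical split keys of an unrooted tree: each edge maps to the tip-label
# set below it, complemented so the lexicographically smallest label is
# never inside the set.
.splitLengths <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  po <- stats::reorder(tree, "postorder")
  keys <- character(nrow(po$edge)); lens <- po$edge.length
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    s <- below[[ch]]
    below[[p]] <- c(below[[p]], s)
    if (anchor %in% s) s <- setdiff(tree$tip.label, s)
    keys[k] <- paste(sort(s), collapse = "\r")
  }
  tapply(lens, keys, sum)
}

#' Branch-score (Euclidean) distance between two trees
#'
#' The square root of the summed squared branch-length differences over the
#' union of bipartitions of the two trees, with a missing bipartition
#' counting as length zero; sensitive to both topology and branch lengths.
#'
#' @param tree1,tree2 \code{phylo} trees on the same leaf set.
#' @return nonnegative numeric scalar.
#' @export
euclideanTreeDistance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label))
    stop("trees have different leaf sets")
  s1 <- .splitLengths(tree1); s2 <- .splitLengths(tree2)
  keys <- union(names(s1), names(s2))
  l1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  l2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sqrt(sum((l1 - l2)^2))
}
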