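# Random trees and alignment simulation under a RateModel.
#
# Topologies are grown by sequential random attachment: each new leaf is
# attached to a branch chosen uniformly among the current branches plus the
# root stem, which samples uniformly among labeled rooted binary topologies.
# Sequences evolve by exact transition-probability sampling: the root state
# is drawn from pi and each child state from the parent's row of P(branch
# length), independently across sites.

#' Random rooted binary tree with uniform branch lengths
#'
#' @param nTaxa number of leaves (>= 2).
#' @param blRange branch-length range, default \code{c(0.01, 0.5)}.
#' @param seed optional RNG seed for reproducibility.
#' @param labels tip labels (default \code{t1..tn}).
#' @return a rooted \code{phylo} tree with \code{2*nTaxa - 2} branches and
#'   \code{nTaxa - 1} internal nodes.
#' @export
randomTree <- function(nTaxa, blRange = c(0.01, 0.5), seed = NULL,
                       labels = paste0("t", seq_len(nTaxa))) {
  if (nTaxa < 2) stop("need at least 2 taxa")
  if (length(blRange) != 2 || blRange[1] > blRange[2] || blRange[1] < 0)
    stop("invalid branch-length range")
  if (!is.null(seed)) set.seed(seed)
  # node ids are allocated sequentially; tips tracked by creation order
  root <- 1L
  parent <- c(1L, 1L); child <- c(2L, 3L)
  tips <- c(2L, 3L)
  nextId <- 4L
  while (length(tips) < nTaxa) {
    leaf <- nextId; mid <- nextId + 1L; nextId <- nextId + 2L
    e <- sample.int(length(parent) + 1L, 1L)
    if (e > length(parent)) {          # attach above the root (root stem)
      parent <- c(parent, mid, mid)
      child <- c(child, root, leaf)
      root <- mid
    } else {                           # split edge e
      old <- child[e]
      child[e] <- mid
      parent <- c(parent, mid, mid)
      child <- c(child, old, leaf)
    }
    tips <- c(tips, leaf)
  }
  # renumber into ape convention: tips 1..n, root n+1, internals follow
  internal <- setdiff(unique(parent), tips)
  internal <- c(root, setdiff(internal, root))
  map <- integer(nextId - 1L)
  map[tips] <- seq_along(tips)
  map[internal] <- nTaxa + seq_along(internal)
  tr <- list(edge = cbind(map[parent], map[child]),
             edge.length = stats::runif(length(parent), blRange[1], blRange[2]),
             tip.label = labels, Nnode = length(internal))
  class(tr) <- "phylo"
  stats::reorder(tr, "cladewise")
}

#' Scale all branch lengths of a tree
#'
#' @param tree a \code{phylo} tree.
#' @param factor positive multiplier.
#' @return the tree with every branch multiplied by \code{factor}.
#' @export
scaleTree <- function(tree, factor) {
  if (factor <= 0) stop("scale factor must be positive")
  tree$edge.length <- tree$edge.length * factor
  tree
}

#' Simulate a rotasequence alignment along a tree
#'
#' Root states are drawn i.i.d. from the model's equilibrium frequencies;
#' each child's state is drawn from the parent's row of P(t) for the
#' connecting branch, independently across sites. With \code{rates}, each
#' site is assigned a rate category uniformly at random and all branches of
#' that site are stretched by the category rate.
#'
#' @param tree a \code{phylo} tree with branch lengths in the model's units.
#' @param model a \linkS4class{RateModel}.
#' @param nSites number of sites.
#' @param seed optional RNG seed.
#' @param rates optional \linkS4class{GammaRates} for among-site rate
#'   heterogeneity.
#' @param recordInternal keep ancestral (internal-node) sequences?
#' @return list with \code{alignment} (tips), \code{internal} (a
#'   \linkS4class{RotaAlignment} of internal-node sequences, labeled by ape
#'   node number, or NULL), and \code{siteRates}.
#' @export
simulateAlignment <- function(tree, model, nSites, seed = NULL, rates = NULL,
                              recordInternal = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ab <- model@alphabet
  n <- length(model@pi)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  dec <- .decomposeModel(model)
  cat_ <- if (is.null(rates)) rep(1L, nSites) else
    sample.int(rates@k, nSites, replace = TRUE)
  rv <- if (is.null(rates)) 1 else rates@rates
  states <- matrix(0L, nn, nSites)
  root <- ntip + 1L
  states[root, ] <- sample.int(n, nSites, replace = TRUE, prob = model@pi)
  cw <- stats::reorder(tree, "cladewise")   # parents before children
  for (k in seq_len(nrow(cw$edge))) {
    p <- cw$edge[k, 1]; ch <- cw$edge[k, 2]; bl <- cw$edge.length[k]
    for (ci in unique(cat_)) {
      sel <- which(cat_ == ci)
      P <- .pmatFromDecomp(dec, bl * rv[ci])
      ps <- states[p, sel]
      # draw child states per parent state
      for (s in unique(ps)) {
        w <- sel[ps == s]
        states[ch, w] <- sample.int(n, length(w), replace = TRUE, prob = P[s, ])
      }
    }
  }
  tipm <- states[seq_len(ntip), , drop = FALSE]
  rownames(tipm) <- tree$tip.label
  alnTips <- rotaAlignment(tipm, ab)
  internal <- NULL
  if (recordInternal) {
    im <- states[(ntip + 1L):nn, , drop = FALSE]
    rownames(im) <- paste0("node", (ntip + 1L):nn)
    internal <- rotaAlignment(im, ab)
  }
  list(alignment = alnTips, internal = internal, siteRates = rv[cat_])
}
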