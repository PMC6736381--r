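# Joint and marginal ancestral state reconstruction on the expanded state
# space, and the leave-leaves-out (LLO) evaluation protocol.
#
# Marginal reconstruction computes, per node and site, the posterior
# distribution over states given all tip data (up/down message passing
# under the reversible model). Joint reconstruction finds the single
# assignment of states to all unobserved nodes maximizing the joint
# probability per site (max-product dynamic programming with traceback,
# ties broken toward the lowest state index).

.nodeId <- function(tree, node) {
  if (is.character(node)) {
    i <- match(node, tree$tip.label)
    if (!is.na(i)) return(i)
    if (grepl("^node[0-9]+$", node)) return(as.integer(sub("node", "", node)))
    stop("node not found: ", node)
  }
  node <- as.integer(node)
  if (node < 1 || node > length(tree$tip.label) + tree$Nnode)
    stop("node not found: ", node)
  node
}

# up/down messages for one rate category, linear space (suitable for the
# modest tree sizes reconstruction is used at).
.messages <- function(po, tipStates, dec, rate, nStates, pi) {
  nn <- max(po$edge); ntip <- nrow(tipStates); ns <- ncol(tipStates)
  E <- po$edge; el <- po$edge.length
  Pmat <- lapply(seq_len(nrow(E)), function(k) .pmatFromDecomp(dec, el[k] * rate))
  upMsg <- vector("list", nn)     # message from child through its pendant edge
  upPart <- vector("list", nn)    # product of children messages at a node
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    msg <- if (ch <= ntip) .tipMessage(Pmat[[k]], tipStates[ch, ], nStates, ns)
    else Pmat[[k]] %*% upPart[[ch]]
    upMsg[[ch]] <- msg
    upPart[[p]] <- if (is.null(upPart[[p]])) msg else upPart[[p]] * msg
  }
  root <- ntip + 1L
  down <- vector("list", nn)
  down[[root]] <- matrix(pi, nStates, ns)
  for (k in rev(seq_len(nrow(E)))) {        # preorder: parents first
    p <- E[k, 1]; ch <- E[k, 2]
    out <- down[[p]]
    for (kk in which(E[, 1] == p)) {
      sib <- E[kk, 2]
      if (sib != ch) out <- out * upMsg[[sib]]
    }
    down[[ch]] <- crossprod(Pmat[[k]], out)
  }
  list(upMsg = upMsg, upPart = upPart, down = down, root = root,
       ntip = ntip)
}

#' Marginal ancestral reconstruction (posterior state distributions)
#'
#' Posterior at a node is the normalized product of the partial likelihoods
#' arriving from all incident subtrees under the reversible model; with
#' gamma rates, categories are mixed by their site likelihoods. Tip nodes
#' may be queried too (useful when their characters are masked, as in the
#' leave-leaves-out protocol): the posterior then reflects the rest of the
#' data through the pendant branch.
#'
#' @inheritParams pruningLoglik
#' @param nodes nodes to reconstruct: ape node numbers, \code{"nodeK"}
#'   labels, or tip labels; default all internal nodes.
#' @return list with \code{posterior} (named list of nStates x nSites
#'   matrices, columns summing to 1) and \code{states} (matrix of
#'   maximum-posterior state codes, rows matching \code{nodes}).
#' @export
marginalReconstruct <- function(tree, aln, model, nodes = NULL, rates = NULL) {
  tipStates <- .alignTipsToTree(tree, aln)
  po <- stats::reorder(tree, "postorder")
  dec <- .decomposeModel(model)
  n <- length(model@pi)
  ntip <- nrow(tipStates)
  if (is.null(nodes)) nodes <- (ntip + 1L):(ntip + tree$Nnode)
  ids <- vapply(nodes, .nodeId, integer(1), tree = tree)
  rv <- if (is.null(rates)) 1 else rates@rates
  ns <- ncol(tipStates)
  num <- lapply(ids, function(i) matrix(0, n, ns))
  for (ci in seq_along(rv)) {
    msg <- .messages(po, tipStates, dec, rv[ci], n, model@pi)
    for (w in seq_along(ids)) {
      id <- ids[w]
      up <- if (id <= ntip) .tipIndicator(tipStates[id, ], n)
      else msg$upPart[[id]]
      num[[w]] <- num[[w]] + (up * msg$down[[id]]) / length(rv)
    }
  }
  posterior <- lapply(num, function(m) sweep(m, 2, colSums(m), "/"))
  names(posterior) <- vapply(ids, function(i)
    if (i <= ntip) tree$tip.label[i] else paste0("node", i), character(1))
  states <- do.call(rbind, lapply(posterior, function(m)
    apply(m, 2, which.max)))
  rownames(states) <- names(posterior)
  list(posterior = posterior, states = states)
}

.tipIndicator <- function(st, nStates) {
  M <- matrix(0, nStates, length(st))
  ok <- st > 0L
  M[cbind(st[ok], which(ok))] <- 1
  M[, !ok] <- 1
  M
}

#' Joint ancestral reconstruction (max-product dynamic programming)
#'
#' Finds, per site, the assignment of states to all internal nodes (and any
#' masked tips) that maximizes the joint probability of tips and ancestors.
#' Ties break toward the lowest state index. Rate heterogeneity is not
#' mixed here; reconstruction uses the single-rate model.
#'
#' @inheritParams pruningLoglik
#' @return list with \code{states} (matrix over all nodes: observed tips
#'   keep their characters, masked tips and internal nodes get
#'   reconstructed states; rows named by tip label or \code{"nodeK"}) and
#'   \code{logProb} (per-site log joint probability of the assignment).
#' @export
jointReconstruct <- function(tree, aln, model) {
  tipStates <- .alignTipsToTree(tree, aln)
  po <- stats::reorder(tree, "postorder")
  dec <- .decomposeModel(model)
  n <- length(model@pi)
  ntip <- nrow(tipStates); ns <- ncol(tipStates)
  nn <- ntip + tree$Nnode
  E <- po$edge; el <- po$edge.length
  Lv <- vector("list", nn); Cv <- vector("list", nn)
  childSum <- vector("list", nn)
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    lP <- log(.pmatFromDecomp(dec, el[k]))
    base <- if (is.null(childSum[[ch]])) matrix(0, n, ns) else childSum[[ch]]
    L <- matrix(0, n, ns); C <- matrix(0L, n, ns)
    for (i in seq_len(n)) {
      cand <- base + lP[i, ]
      C[i, ] <- apply(cand, 2, which.max)
      L[i, ] <- cand[cbind(C[i, ], seq_len(ns))]
    }
    if (ch <= ntip) {            # observed sites constrain the choice
      st <- tipStates[ch, ]
      obs <- which(st > 0L)
      if (length(obs)) {
        C[, obs] <- matrix(st[obs], n, length(obs), byrow = TRUE)
        L[, obs] <- lP[, st[obs], drop = FALSE]
      }
    }
    Lv[[ch]] <- L; Cv[[ch]] <- C
    childSum[[p]] <- if (is.null(childSum[[p]])) L else childSum[[p]] + L
  }
  root <- ntip + 1L
  rootScore <- childSum[[root]] + log(model@pi)
  states <- matrix(0L, nn, ns)
  states[root, ] <- apply(rootScore, 2, which.max)
  logProb <- rootScore[cbind(states[root, ], seq_len(ns))]
  for (k in rev(seq_len(nrow(E)))) {       # preorder traceback
    p <- E[k, 1]; ch <- E[k, 2]
    states[ch, ] <- Cv[[ch]][cbind(states[p, ], seq_len(ns))]
  }
  rn <- c(tree$tip.label, paste0("node", (ntip + 1L):nn))
  rownames(states) <- rn
  list(states = states, logProb = logProb)
}

#' Leave-leaves-out reconstruction of a terminal sequence
#'
#' Removes a pair of sibling terminal taxa from the alignment (their
#' characters become unknown), reconstructs with the chosen algorithm on
#' the full tree (original branch lengths retained), and returns the
#' reconstructed sequence at the first taxon of the pair. Sites at which
#' every remaining taxon is gapped or unknown are returned as UNKNOWN.
#'
#' @inheritParams pruningLoglik
#' @param pair character vector of two sibling tip labels; the first is the
#'   reconstruction target.
#' @param algorithm \code{"marginal"} or \code{"joint"}.
#' @return integer vector of reconstructed state codes for the target.
#' @export
leaveLeavesOut <- function(tree, aln, pair, model,
                           algorithm = c("marginal", "joint"), rates = NULL) {
  algorithm <- match.arg(algorithm)
  if (length(pair) != 2L) stop("pair must name two tips")
  ids <- match(pair, tree$tip.label)
  if (anyNA(ids)) stop("tips not in tree: ",
                       paste(pair[is.na(ids)], collapse = ", "))
  par <- vapply(ids, function(i)
    as.numeric(tree$edge[tree$edge[, 2] == i, 1]), numeric(1))
  if (par[1] != par[2]) stop("tips ", pair[1], " and ", pair[2],
                             " are not siblings")
  m <- aln@states
  m[match(pair, rownames(m)), ] <- UNK_CODE
  aln2 <- rotaAlignment(m, aln@alphabet)
  others <- m[!rownames(m) %in% pair, , drop = FALSE]
  dead <- apply(others <= 0L, 2, all)
  rec <- if (algorithm == "joint")
    jointReconstruct(tree, aln2, model)$states[pair[1], ]
  else
    marginalReconstruct(tree, aln2, model, nodes = pair[1],
                        rates = rates)$states[1, ]
  rec[dead] <- UNK_CODE
  as.integer(rec)
}

#' Percent identity between an inferred and a reference sequence
#'
#' Positions where either sequence is gapped/unknown are excluded from the
#' denominator. With \code{mask = TRUE} both sequences are collapsed to
#' amino-acid states first, so the masked accuracy is never below the
#' full-state accuracy.
#'
#' @param inferred,reference integer state-code vectors of equal length.
#' @param alphabet the \linkS4class{RotamerAlphabet} (needed for masking).
#' @param mask compare amino-acid states instead of full rotamer states?
#' @return percent identity (0..100), NA if no comparable positions.
#' @export
reconstructionAccuracy <- function(inferred, reference, alphabet = NULL,
                                   mask = FALSE) {
  if (length(inferred) != length(reference))
    stop("sequences differ in length")
  if (mask) {
    if (is.null(alphabet)) stop("alphabet required for masked accuracy")
    inferred <- maskRotamers(inferred, alphabet)
    reference <- maskRotamers(reference, alphabet)
  }
  ok <- inferred > 0L & reference > 0L
  if (!any(ok)) return(NA_real_)
  100 * mean(inferred[ok] == reference[ok])
}
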