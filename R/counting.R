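# Tabulating substitution counts from rotasequence alignments.
#
# Pairs of sequences to compare are chosen by a circular tour through a
# neighbor-joining tree of the family: consecutive leaves in the tree's
# planar (depth-first) leaf order, including the wrap-around pair, so that
# every leaf enters exactly two comparisons and each observed difference is
# counted at most twice. Pairs below 75% rotasequence identity are skipped
# to limit multiple-hit artefacts. Counts accumulate symmetrically: an
# observed i/j difference adds 1 to both n_ij and n_ji, a conserved site
# adds 2 to n_ii, so row sums count all observations of each state.

#' Pairwise p-distances of an alignment
#'
#' 1 - identity over sites where neither sequence has a gap or unknown
#' state (pairwise deletion). Taxa are ordered lexicographically so the
#' resulting neighbor-joining tree does not depend on input order.
#'
#' @param aln a \linkS4class{RotaAlignment}.
#' @return symmetric distance matrix.
#' @export
pDistance <- function(aln) {
  m <- aln@states[order(rownames(aln@states)), , drop = FALSE]
  nt <- nrow(m)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- m[i, ] > 0L & m[j, ] > 0L
    if (!any(ok)) stop("no comparable sites between ", rownames(m)[i],
                       " and ", rownames(m)[j])
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); two taxa yield the
#' trivial one-edge tree. All-zero distances are accepted (and produce a
#' zero-length tree).
#'
#' @param d symmetric nonnegative distance matrix with dimnames.
#' @return an unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d) || any(!is.finite(d))) stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (nrow(d) == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Circular (depth-first) leaf order of a tree
#'
#' @param tree a \code{phylo} tree.
#' @return character vector of tip labels in planar traversal order; the
#'   cyclic successor pairs (including wrap-around) define the comparisons.
#' @export
circularLeafOrder <- function(tree) {
  cw <- stats::reorder(tree, "cladewise")
  tips <- cw$edge[cw$edge[, 2] <= length(tree$tip.label), 2]
  tree$tip.label[tips]
}

#' Substitution counts from one aligned sequence pair
#'
#' Sites where either sequence is gapped or unknown are ignored. If the
#' identity over compared sites falls below \code{identityMin} the pair is
#' skipped (returns \code{NULL}). Otherwise a symmetric count increment is
#' returned: +1 to each of n_ij and n_ji per differing site, +2 to n_ii per
#' conserved site.
#'
#' @param a,b integer state-code vectors of equal length.
#' @param nStates number of alphabet states.
#' @param identityMin identity threshold (default 0.75); pairs at exactly
#'   the threshold are counted.
#' @return integer count matrix, or \code{NULL} when skipped; the realized
#'   identity is attached as attribute \code{"identity"}.
#' @export
pairCounts <- function(a, b, nStates, identityMin = 0.75) {
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a > 0L & b > 0L
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(NULL)
  ident <- mean(a == b)
  if (ident < identityMin) return(NULL)
  M <- matrix(0L, nStates, nStates)
  idx <- cbind(a, b)
  for (r in seq_len(nrow(idx))) {
    M[idx[r, 1], idx[r, 2]] <- M[idx[r, 1], idx[r, 2]] + 1L
    M[idx[r, 2], idx[r, 1]] <- M[idx[r, 2], idx[r, 1]] + 1L
  }
  attr(M, "identity") <- ident
  M
}

#' Accumulate substitution counts over a family alignment
#'
#' Builds the neighbor-joining tree from p-distances, takes the circular
#' tour, and sums \code{\link{pairCounts}} over consecutive leaf pairs
#' (wrap-around included, deduplicated for two taxa).
#'
#' @param aln a \linkS4class{RotaAlignment} with at least two taxa.
#' @param identityMin identity threshold for pair inclusion.
#' @return count matrix with state labels; attributes \code{"nPairs"} and
#'   \code{"nSkipped"} record the tour bookkeeping.
#' @export
accumulateFamily <- function(aln, identityMin = 0.75) {
  nt <- nrow(aln@states)
  if (nt < 2L) stop("need at least 2 taxa")
  n <- length(aln@alphabet@labels)
  ord <- if (nt == 2L) rownames(aln@states) else
    circularLeafOrder(njTree(pDistance(aln)))
  pairs <- cbind(ord, c(ord[-1], ord[1]))
  key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  M <- matrix(0, n, n, dimnames = list(aln@alphabet@labels,
                                       aln@alphabet@labels))
  skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    inc <- pairCounts(aln@states[pairs[r, 1], ], aln@states[pairs[r, 2], ],
                      n, identityMin)
    if (is.null(inc)) skipped <- skipped + 1L else M <- M + inc
  }
  attr(M, "nPairs") <- nrow(pairs)
  attr(M, "nSkipped") <- skipped
  M
}

#' Lump expanded-state counts to amino-acid counts
#'
#' Sums each (A, A') rotamer submatrix of an expanded count matrix into a
#' single amino-acid-level cell.
#'
#' @param counts expanded count matrix in alphabet state order.
#' @param alphabet the \linkS4class{RotamerAlphabet}.
#' @return amino-acid-level count matrix.
#' @export
lumpCounts <- function(counts, alphabet) {
  f <- factor(alphabet@aa, levels = unique(alphabet@aa))
  agg <- rowsum(t(rowsum(counts, f)), f)
  m <- as.matrix(agg)[levels(f), levels(f), drop = FALSE]
  dimnames(m) <- list(maskedAlphabet(alphabet)@labels,
                      maskedAlphabet(alphabet)@labels)
  m
}

#' Normalize expanded counts against amino-acid counts
#'
#' Rescales every (A, A') rotamer submatrix of the expanded count matrix so
#' that it sums to the corresponding amino-acid count n_AA', removing the
#' composition bias introduced by structure-quality filtering while
#' preserving the within-submatrix rotamer exchange pattern. Amino-acid
#' marginals of the result equal those of the 20-state counts.
#'
#' @param counts expanded (e.g. 55-state) symmetric count matrix.
#' @param counts20 amino-acid-level symmetric count matrix, rows/cols in
#'   \code{aaLevels(alphabet)} order.
#' @param alphabet the expanded \linkS4class{RotamerAlphabet}.
#' @param pseudocount if > 0, a submatrix with zero total but positive
#'   amino-acid count is filled uniformly with this value before rescaling;
#'   the default 0 makes that situation a hard error.
#' @return normalized (real-valued) count matrix.
#' @export
normalizeCounts <- function(counts, counts20, alphabet, pseudocount = 0) {
  .assertCounts(counts); .assertCounts(counts20)
  lev <- unique(alphabet@aa)
  if (!all(dim(counts20) == length(lev)))
    stop("counts20 dimension does not match the amino-acid alphabet")
  idx <- split(seq_along(alphabet@aa), factor(alphabet@aa, levels = lev))
  out <- counts
  for (i in seq_along(lev)) for (j in i:length(lev)) {
    ri <- idx[[i]]; rj <- idx[[j]]
    s <- sum(counts[ri, rj])
    target <- counts20[i, j]
    if (s == 0) {
      if (target > 0) {
        if (pseudocount <= 0)
          stop("no expanded counts for amino-acid pair ", lev[i], "/",
               lev[j], " but 20-state count is ", target,
               "; supply a pseudocount to spread it")
        out[ri, rj] <- pseudocount
        if (i != j) out[rj, ri] <- pseudocount
        s <- sum(out[ri, rj])
      } else next
    }
    out[ri, rj] <- out[ri, rj] * (target / s)
    if (i != j) out[rj, ri] <- t(out[ri, rj])
  }
  out
}
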