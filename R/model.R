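# From symmetric substitution counts to scaled reversible rate matrices.
#
# The pipeline mirrors classical count-based ("Dayhoff-like") estimation:
# the instantaneous rate of i -> j is the number of observed i/j exchanges
# as a proportion of all observations of i (conserved sites included), the
# equilibrium frequencies are the count row sums, and the matrix is then
# rescaled so that unit time corresponds to one expected substitution
# (rotamer-unit scaling, constant rho) and further so that unit time
# corresponds to one expected amino-acid-changing substitution
# (superscaling, constant rho*). For a plain amino-acid alphabet every
# substitution changes the amino acid, so rho* = 1 and the two units agree.

.assertCounts <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("counts must be a square matrix")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("counts must be symmetric")
  invisible(counts)
}

#' Instantaneous rates and frequencies from normalized counts
#'
#' Off-diagonal rate \code{q_ij = n_ij / sum_k n_ik} (the denominator
#' includes the diagonal conservation counts), diagonal closed so rows sum
#' to zero, and \code{pi_i} proportional to row sums. Symmetric counts give
#' a time-reversible matrix by construction.
#'
#' @param counts symmetric nonnegative matrix with positive row sums.
#' @return list with components \code{Q} and \code{pi}.
#' @export
countsToIRM <- function(counts) {
  .assertCounts(counts)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    bad <- rownames(counts)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("zero count row sum for state(s): ", paste(bad, collapse = ", "))
  }
  Q <- counts / rs
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  list(Q = Q, pi = rs / sum(counts))
}

#' Rotamer-unit scaling: one expected substitution per unit time
#'
#' Divides Q by the total equilibrium rate \code{rho = |sum_i pi_i q_ii|},
#' so that at equilibrium the scaled matrix produces one expected state
#' substitution per unit of time.
#'
#' @param Q rate matrix (zero row sums).
#' @param pi equilibrium frequencies.
#' @return list with components \code{Q} (scaled) and \code{rho}.
#' @export
scaleRotamerUnit <- function(Q, pi) {
  rho <- abs(sum(pi * diag(Q)))
  if (rho == 0) stop("zero process: total substitution rate is 0")
  list(Q = Q / rho, rho = rho)
}

#' Superscaling: one expected amino-acid change per unit time
#'
#' Computes \code{rho*}, the equilibrium proportion of state substitutions
#' in which the amino acid changes, and divides the rotamer-unit-scaled
#' matrix by it. At equilibrium the superscaled matrix produces exactly one
#' amino-acid-changing event and \code{(1-rho*)/rho*} pure-rotamer events
#' per unit time, making branch lengths comparable with 20-state models.
#'
#' @param Q rotamer-unit-scaled rate matrix.
#' @param pi equilibrium frequencies.
#' @param alphabet the \linkS4class{RotamerAlphabet} defining which states
#'   share an amino acid.
#' @return list with components \code{Q} (superscaled) and \code{rhoStar}.
#' @export
superscaleIRM <- function(Q, pi, alphabet) {
  aa <- aminoAcids(alphabet)
  diff <- outer(aa, aa, "!=")
  rhoStar <- sum(pi * rowSums(Q * diff))
  if (rhoStar <= 0) stop("zero amino-acid-changing rate; cannot superscale")
  list(Q = Q / rhoStar, rhoStar = rhoStar)
}

.newRateModel <- function(alphabet, Q, pi, scaling, rho = NA_real_,
                          rhoStar = NA_real_) {
  dimnames(Q) <- list(alphabet@labels, alphabet@labels)
  S <- sweep(Q, 2, pi, "/")
  diag(S) <- 0
  S <- (S + t(S)) / 2
  names(pi) <- alphabet@labels
  dimnames(S) <- dimnames(Q)
  new("RateModel", alphabet = alphabet, Q = Q, pi = pi, S = S,
      rho = rho, rhoStar = rhoStar, scaling = scaling)
}

#' Build a scaled reversible model from substitution counts
#'
#' Runs the full estimation pipeline: rates and frequencies from the count
#' matrix, rotamer-unit scaling, and (optionally) superscaling.
#'
#' @param counts symmetric nonnegative count matrix in alphabet state order.
#' @param alphabet the matching \linkS4class{RotamerAlphabet}.
#' @param scaling target time unit: \code{"superscaled"} (default),
#'   \code{"rotamer"} or \code{"none"}.
#' @return a \linkS4class{RateModel}.
#' @examples
#' fix <- toyModel(c(3, 2, 1), seed = 1)
#' countsToRateModel(fix$counts, fix$alphabet)
#' @export
countsToRateModel <- function(counts, alphabet,
                              scaling = c("superscaled", "rotamer", "none")) {
  scaling <- match.arg(scaling)
  if (nrow(counts) != length(alphabet@labels))
    stop("counts dimension does not match the alphabet")
  est <- countsToIRM(counts)
  Q <- est$Q; pi <- est$pi
  rho <- NA_real_; rhoStar <- NA_real_
  if (scaling != "none") {
    sc <- scaleRotamerUnit(Q, pi); Q <- sc$Q; rho <- sc$rho
  }
  if (scaling == "superscaled") {
    ss <- superscaleIRM(Q, pi, alphabet); Q <- ss$Q; rhoStar <- ss$rhoStar
  }
  .newRateModel(alphabet, Q, pi, scaling, rho, rhoStar)
}

#' Rebuild a model from exchangeabilities and frequencies (the +F mechanism)
#'
#' Inverts \code{s_ij = q_ij / pi_j}: sets \code{q_ij = s_ij * pi_j}, closes
#' the diagonal, and rescales per the requested convention. Supplying
#' frequencies estimated from a particular data set together with general
#' exchangeabilities is the standard "+F" parametrization.
#'
#' @param S symmetric nonnegative exchangeability matrix.
#' @param pi frequencies to combine with \code{S}.
#' @param alphabet the state space.
#' @param rescale \code{"superscaled"}, \code{"rotamer"} or \code{"none"}.
#' @return a \linkS4class{RateModel}.
#' @export
exchToRateModel <- function(S, pi, alphabet,
                            rescale = c("superscaled", "rotamer", "none")) {
  rescale <- match.arg(rescale)
  n <- length(alphabet@labels)
  if (!all(dim(S) == n)) stop("dimension mismatch between S and alphabet")
  if (length(pi) != n) stop("dimension mismatch between S and pi")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("exchangeability matrix must be symmetric")
  if (any(pi <= 0)) stop("frequencies must be positive")
  pi <- pi / sum(pi)
  Q <- sweep(S, 2, pi, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rho <- NA_real_; rhoStar <- NA_real_
  if (rescale != "none") {
    sc <- scaleRotamerUnit(Q, pi); Q <- sc$Q; rho <- sc$rho
  }
  if (rescale == "superscaled") {
    ss <- superscaleIRM(Q, pi, alphabet); Q <- ss$Q; rhoStar <- ss$rhoStar
  }
  .newRateModel(alphabet, Q, pi, rescale, rho, rhoStar)
}

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "RateModel", function(x) x@Q)

#' @rdname stateFreqs
#' @export
setMethod("stateFreqs", "RateModel", function(x) x@pi)

#' @rdname exchangeabilities
#' @export
setMethod("exchangeabilities", "RateModel", function(x) x@S)

#' @rdname alphabet
#' @export
setMethod("alphabet", "RateModel", function(x) x@alphabet)

#' @rdname nStates
#' @export
setMethod("nStates", "RateModel", function(x) length(x@alphabet@labels))

setMethod("show", "RateModel", function(object) {
  n <- length(object@alphabet@labels)
  cat("RateModel over", n, "states; scaling:", object@scaling, "\n")
  if (!is.na(object@rho)) cat("  rho =", format(object@rho, digits = 6), "\n")
  if (!is.na(object@rhoStar))
    cat("  rho* =", format(object@rhoStar, digits = 6),
        " (1/rho* =", format(1 / object@rhoStar, digits = 4), ")\n")
})
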