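# Model fit comparison across state spaces.
#
# 20-state and 55-state models live in different state spaces, so their
# likelihoods are not directly comparable. Whelan's state-space correction
# maps a compound-alphabet (amino-acid) likelihood to the distinct
# (expanded) alphabet by multiplying, for every observed tip character, the
# ratio of the distinct state's equilibrium frequency to its compound
# state's frequency. AIC computed on such corrected likelihoods is the
# "state-corrected AIC". Two reference expansions embed a 20-state model in
# the expanded space: a uniform spread of the (reconstructed) counts over
# each rotamer submatrix, and a frequency-weighted spread.

#' Akaike information criterion
#' @param logL maximized log-likelihood.
#' @param k number of estimated parameters.
#' @return \code{2k - 2 logL}.
#' @export
aic <- function(logL, k) {
  if (k < 0) stop("k must be nonnegative")
  2 * k - 2 * logL
}

#' State-space-corrected log-likelihood of a compound (amino-acid) model
#'
#' Adds, for every non-gap/non-unknown tip character of the expanded-state
#' alignment, \code{log(pi55[d] / pi20[c])} where d is the observed
#' expanded state and c its amino-acid state; gaps and unknowns contribute
#' nothing.
#'
#' @param logL20 log-likelihood of the masked alignment under the 20-state
#'   model.
#' @param aln the expanded-state \linkS4class{RotaAlignment}.
#' @param pi55 equilibrium frequencies of the distinct (expanded) model.
#' @param pi20 equilibrium frequencies of the compound model, in
#'   \code{aaLevels} order.
#' @return corrected log-likelihood (distinct-alphabet scale).
#' @export
stateCorrectedLoglik <- function(logL20, aln, pi55, pi20) {
  ab <- aln@alphabet
  map <- maskIndex(ab)
  st <- aln@states[aln@states > 0L]
  if (!length(st)) return(logL20)
  if (any(pi20[map[st]] <= 0) || any(pi55[st] <= 0))
    stop("zero equilibrium frequency for an observed state")
  logL20 + sum(log(pi55[st] / pi20[map[st]]))
}

#' Reconstruct symmetric counts from exchangeabilities and frequencies
#'
#' Reverses the count-to-exchangeability pipeline. Off the diagonal the
#' unique symmetric solution (up to scale, which is irrelevant after rate
#' scaling) is \code{n_ij = pi_i s_ij pi_j}. The diagonal (conservation)
#' counts are chosen so that row sums are proportional to \code{pi}, which
#' is what the forward pipeline guarantees; pushing the result back through
#' the estimation equations then recovers the model exactly (up to the
#' overall rate absorbed by scaling).
#'
#' @param S symmetric exchangeability matrix.
#' @param pi equilibrium frequencies.
#' @return symmetric nonnegative matrix with strictly positive row sums.
#' @export
countsFromExchangeabilities <- function(S, pi) {
  N <- S * outer(pi, pi)
  diag(N) <- 0
  r <- rowSums(N) / pi           # total rate out of each state, up to scale
  K <- 2 * max(r)
  diag(N) <- pi * (K - r)
  N
}

.counts20From <- function(x) {
  if (is(x, "RateModel")) countsFromExchangeabilities(x@S, x@pi) else x
}

#' Uniform expansion of a 20-state model into the expanded state space
#'
#' Spreads each amino-acid-level count uniformly over the corresponding
#' rotamer submatrix (dividing by the product of the submatrix dimensions),
#' then applies the standard estimation pipeline. The result is the
#' most-uninformed expression of the 20-state model in the expanded space:
#' its equilibrium frequencies are \code{pi_A / |R_A|} and its rates toward
#' any (A', R') equal the amino-acid rate divided by \code{|R_A'|}, so the
#' expanded chain lumps exactly onto the amino-acid chain.
#'
#' @param x amino-acid count matrix in \code{aaLevels(alphabet)} order, or a
#'   20-state \linkS4class{RateModel} (counts are then reconstructed from
#'   its exchangeabilities).
#' @param alphabet the expanded target \linkS4class{RotamerAlphabet}.
#' @param scaling time-unit convention of the result.
#' @return an expanded \linkS4class{RateModel}.
#' @export
expandUniform <- function(x, alphabet,
                          scaling = c("superscaled", "rotamer", "none")) {
  N20 <- .counts20From(x)
  map <- maskIndex(alphabet)
  mult <- rotamerMultiplicity(alphabet)
  Nbar <- N20[map, map] / outer(mult[map], mult[map])
  dimnames(Nbar) <- list(alphabet@labels, alphabet@labels)
  countsToRateModel(Nbar, alphabet, match.arg(scaling))
}

#' Frequency-weighted expansion of a 20-state model
#'
#' Spreads each amino-acid-level count over the rotamer submatrix in
#' proportion to the product of supplied expanded-state frequencies:
#' \code{nbar_ij = pi55_i pi55_j n_AA'}. The expansion is informed about
#' rotamer state frequencies but not about rotamer replacement preferences.
#'
#' @inheritParams expandUniform
#' @param pi55 expanded-state frequencies (e.g. from a reference expanded
#'   model).
#' @return an expanded \linkS4class{RateModel}.
#' @export
expandByFreq <- function(x, pi55, alphabet,
                         scaling = c("superscaled", "rotamer", "none")) {
  N20 <- .counts20From(x)
  map <- maskIndex(alphabet)
  if (length(pi55) != length(map)) stop("pi55 length does not match alphabet")
  Nbar <- N20[map, map] * outer(pi55, pi55)
  dimnames(Nbar) <- list(alphabet@labels, alphabet@labels)
  countsToRateModel(Nbar, alphabet, match.arg(scaling))
}

#' Kullback-Leibler information loss of lumping, per start state
#'
#' For a start state (A, R) of the expanded model, compares the amino-acid
#' distribution reached after time t (expanded transition probabilities
#' summed over the rotamer configurations of each target amino acid) with
#' the corresponding row of the 20-state model, in bits. Both models must
#' use the same time units (superscaled recommended). A zero 20-state
#' probability facing nonzero expanded mass yields \code{Inf}.
#'
#' @param model55 expanded \linkS4class{RateModel}.
#' @param model20 amino-acid \linkS4class{RateModel} whose states are
#'   \code{aaLevels(alphabet(model55))}.
#' @param state start state index (or label) in the expanded alphabet.
#' @param t evolutionary time (>= 0).
#' @return KL divergence in bits.
#' @export
klDivergence <- function(model55, model20, state, t) {
  if (is.character(state)) state <- match(state, model55@alphabet@labels)
  kl <- .klAllStates(model55, model20, t)
  kl[state]
}

.klAllStates <- function(model55, model20, t, dec55 = NULL, dec20 = NULL) {
  if (t < 0) stop("t must be nonnegative")
  ab <- model55@alphabet
  map <- maskIndex(ab)
  if (is.null(dec55)) dec55 <- .decomposeModel(model55)
  if (is.null(dec20)) dec20 <- .decomposeModel(model20)
  P55 <- .pmatFromDecomp(dec55, t)
  P20 <- .pmatFromDecomp(dec20, t)
  # aggregate expanded rows over target rotamer configurations
  agg <- t(rowsum(t(P55), factor(map, levels = seq_along(unique(map)))))
  ref <- P20[map, , drop = FALSE]
  term <- agg * log2(agg / ref)
  term[agg < 1e-14] <- 0            # zero mass contributes nothing
  term[agg >= 1e-14 & ref == 0] <- Inf
  rowSums(term)
}

#' Frequency-weighted KL information-loss profile over time
#'
#' Averages \code{\link{klDivergence}} over all expanded start states,
#' weighted by the expanded model's equilibrium frequencies, on a grid of
#' times.
#'
#' @inheritParams klDivergence
#' @param tGrid time grid; default 200 log-spaced points in [0.01, 5].
#' @return data.frame with columns \code{t} and \code{bits}; the per-state
#'   divergence matrix is attached as attribute \code{"perState"}.
#' @export
klProfile <- function(model55, model20,
                      tGrid = exp(seq(log(0.01), log(5), length.out = 200))) {
  dec55 <- .decomposeModel(model55)
  dec20 <- .decomposeModel(model20)
  per <- vapply(tGrid, function(t)
    .klAllStates(model55, model20, t, dec55, dec20),
    numeric(length(model55@pi)))
  prof <- as.numeric(model55@pi %*% per)
  out <- data.frame(t = tGrid, bits = prof)
  attr(out, "perState") <- per
  out
}

#' Compare model fit across state spaces on one data set
#'
#' Computes, for each model, the log-likelihood of the alignment on the
#' tree (masking the alignment for amino-acid-level models and applying the
#' state-space correction with the reference expanded frequencies), and the
#' resulting (state-corrected) AIC. Empirical fixed-rate models are
#' compared with the same parameter count k (branch lengths, plus any
#' explicitly counted extras), so the ranking reflects the likelihoods.
#'
#' @param aln expanded-state \linkS4class{RotaAlignment}.
#' @param tree \code{phylo} tree.
#' @param models named list of \linkS4class{RateModel}s; amino-acid-level
#'   models are detected by their state count.
#' @param rates optional \linkS4class{GammaRates} shared by all models.
#' @param kExtra additional parameter count per model (named numeric,
#'   default 0), e.g. 1 for an estimated gamma shape.
#' @return data.frame: model, states, rawLogLik, correctedLogLik, k, AIC.
#' @export
compareModels <- function(aln, tree, models, rates = NULL, kExtra = NULL) {
  kBase <- length(tree$edge.length)
  masked <- maskRotamers(aln)
  res <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    nst <- length(m@alphabet@labels)
    if (nst == length(aln@alphabet@labels)) {
      ll <- pruningLoglik(tree, aln, m, rates)$logLik
      cll <- ll
    } else if (nst == length(masked@alphabet@labels)) {
      ll <- pruningLoglik(tree, masked, m, rates)$logLik
      # correction needs expanded-state frequencies: take them from the
      # first expanded model in the list
      exp1 <- Filter(function(z)
        length(z@alphabet@labels) == length(aln@alphabet@labels), models)
      if (!length(exp1))
        stop("corrected likelihood needs at least one expanded model for ",
             "reference frequencies")
      cll <- stateCorrectedLoglik(ll, aln, exp1[[1]]@pi, m@pi)
    } else stop("model '", nm, "' matches neither state space")
    k <- kBase + if (!is.null(kExtra) && nm %in% names(kExtra)) kExtra[[nm]] else 0
    data.frame(model = nm, states = nst, rawLogLik = ll,
               correctedLogLik = cll, k = k, AIC = aic(cll, k))
  })
  do.call(rbind, res)
}
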