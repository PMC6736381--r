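# Integer codes used in state matrices alongside 1-based alphabet indices.
GAP_CODE <- 0L
UNK_CODE <- -1L
GAP_CHAR <- "-"
UNK_CHAR <- "?"

#' RotamerAlphabet: an expanded (amino acid, chi1 configuration) state set
#'
#' Each state pairs an amino acid with a chi1 rotamer configuration index.
#' Amino acids without a rotatable chi1 (alanine, glycine) contribute a
#' single state with an \code{NA} rotamer index; proline contributes two
#' states; all other residues three. The class also represents plain
#' amino-acid alphabets (every rotamer index \code{NA}) and reduced "toy"
#' alphabets used for testing, so that every matrix and alignment operation
#' is generic over the state space.
#'
#' @slot labels display labels, e.g. \code{"ARG1"} or \code{"ALA"}.
#' @slot aa one-letter amino-acid code per state.
#' @slot rot integer chi1 configuration index per state (\code{NA} if none).
#' @slot chars single-character code per state (file dialect 1).
#' @slot tokens two-token code per state, amino-acid letter plus digit or
#'   \code{"-"} (file dialect 2), e.g. \code{"R2"}, \code{"A-"}.
#' @export
setClass("RotamerAlphabet",
  representation(labels = "character", aa = "character", rot = "integer",
                 chars = "character", tokens = "character"))

setValidity("RotamerAlphabet", function(object) {
  n <- length(object@labels)
  if (length(object@aa) != n || length(object@rot) != n ||
      length(object@chars) != n || length(object@tokens) != n)
    return("all slots must have equal length")
  if (anyDuplicated(object@labels)) return("duplicated state labels")
  if (anyDuplicated(object@chars)) return("duplicated single-character codes")
  if (anyDuplicated(object@tokens)) return("duplicated state tokens")
  if (any(nchar(object@chars) != 1L)) return("state chars must be single characters")
  if (any(object@chars %in% c(GAP_CHAR, UNK_CHAR)))
    return("state chars must not collide with gap/unknown symbols")
  bad <- !is.na(object@rot) & !(object@rot %in% 1:3)
  if (any(bad)) return("rotamer indices must be in 1..3 or NA")
  TRUE
})

#' RotaAlignment: a rectangular alignment over a RotamerAlphabet
#'
#' Holds taxa-by-sites integer state indices (1-based into the alphabet),
#' with 0 encoding a gap and -1 an unknown state.
#'
#' @slot states integer matrix, rows named by taxon.
#' @slot alphabet the \linkS4class{RotamerAlphabet} the states refer to.
#' @export
setClass("RotaAlignment",
  representation(states = "matrix", alphabet = "RotamerAlphabet"))

setValidity("RotaAlignment", function(object) {
  m <- object@states
  if (!is.integer(m)) return("state matrix must be integer")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxa must be uniquely labeled")
  n <- length(object@alphabet@labels)
  if (any(m > n | m < UNK_CODE, na.rm = TRUE) || anyNA(m))
    return("state indices out of range for the alphabet")
  TRUE
})

#' RateModel: a reversible continuous-time substitution model
#'
#' Couples an instantaneous rate matrix Q (zero row sums), its equilibrium
#' frequencies pi, and the symmetric exchangeabilities \code{s_ij = q_ij /
#' pi_j}. The \code{scaling} slot records the time-unit convention:
#' \code{"none"} (raw per-observation rates), \code{"rotamer"} (one expected
#' state substitution per unit time at equilibrium) or \code{"superscaled"}
#' (one expected amino-acid-changing substitution per unit time, making
#' branch lengths comparable across state spaces). \code{rho} and
#' \code{rhoStar} store the constants divided out at each stage.
#'
#' @slot alphabet the state space.
#' @slot Q instantaneous rate matrix.
#' @slot pi equilibrium frequencies.
#' @slot S symmetric exchangeability matrix (zero diagonal).
#' @slot rho rotamer-unit scaling constant (NA if not applied).
#' @slot rhoStar amino-acid superscaling constant (NA if not applied).
#' @slot scaling one of \code{"none"}, \code{"rotamer"}, \code{"superscaled"}.
#' @export
setClass("RateModel",
  representation(alphabet = "RotamerAlphabet", Q = "matrix", pi = "numeric",
                 S = "matrix", rho = "numeric", rhoStar = "numeric",
                 scaling = "character"))

setValidity("RateModel", function(object) {
  n <- length(object@alphabet@labels)
  if (!all(dim(object@Q) == n)) return("Q dimension does not match alphabet")
  if (length(object@pi) != n) return("pi length does not match alphabet")
  if (any(object@pi <= 0)) return("equilibrium frequencies must be positive")
  if (abs(sum(object@pi) - 1) > 1e-8) return("pi must sum to 1")
  qmax <- max(1, max(abs(object@Q)))
  if (max(abs(rowSums(object@Q))) > 1e-8 * qmax)
    return("rows of Q must sum to 0")
  off <- object@Q; diag(off) <- 0
  if (min(off) < -1e-12 * qmax)
    return("off-diagonal rates must be nonnegative")
  db <- object@pi * object@Q
  if (max(abs(db - t(db))) > 1e-8 * max(abs(db)))
    return("detailed balance (reversibility) violated")
  if (!object@scaling %in% c("none", "rotamer", "superscaled"))
    return("unknown scaling convention")
  TRUE
})

#' GammaRates: discretized gamma among-site rate heterogeneity
#'
#' Equal-probability categories whose rates are the within-bin means of a
#' Gamma(alpha, alpha) distribution, so the mean rate is 1.
#'
#' @slot alpha shape parameter.
#' @slot k number of categories.
#' @slot rates per-category rates (mean 1, equal weights).
#' @export
setClass("GammaRates",
  representation(alpha = "numeric", k = "integer", rates = "numeric"))

setValidity("GammaRates", function(object) {
  if (object@alpha <= 0) return("alpha must be positive")
  if (length(object@rates) != object@k) return("rates length must equal k")
  if (abs(mean(object@rates) - 1) > 1e-8) return("category rates must average 1")
  TRUE
})
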