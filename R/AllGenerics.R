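#' @import methods
NULL

#' Number of states in an alphabet or model
#'
#' @param x a \linkS4class{RotamerAlphabet}, \linkS4class{RotaAlignment} or
#'   \linkS4class{RateModel}.
#' @return integer scalar.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' State labels (display form, e.g. \code{"ARG1"}, \code{"ALA"})
#' @param x an alphabet-bearing object.
#' @return character vector, one entry per state.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' Two-token state codes (e.g. \code{"R1"}, \code{"A-"})
#' @param x an alphabet-bearing object.
#' @return character vector, one entry per state.
#' @export
setGeneric("stateTokens", function(x) standardGeneric("stateTokens"))

#' Single-character state codes
#' @param x an alphabet-bearing object.
#' @return character vector of single characters, one per state.
#' @export
setGeneric("stateChars", function(x) standardGeneric("stateChars"))

#' Per-state amino-acid (one-letter) codes
#' @param x an alphabet-bearing object.
#' @return character vector, one letter per state.
#' @export
setGeneric("aminoAcids", function(x) standardGeneric("aminoAcids"))

#' Per-state chi1 rotamer indices (NA for states without a side-chain chi1)
#' @param x an alphabet-bearing object.
#' @return integer vector, one entry per state.
#' @export
setGeneric("rotamerIndices", function(x) standardGeneric("rotamerIndices"))

#' Distinct amino-acid letters, in state order
#' @param x an alphabet-bearing object.
#' @return character vector of unique amino-acid letters.
#' @export
setGeneric("aaLevels", function(x) standardGeneric("aaLevels"))

#' Collapse an expanded alphabet to its amino-acid alphabet
#'
#' Returns the alphabet obtained by merging all rotamer configurations of
#' each amino acid into a single state.
#' @param x a \linkS4class{RotamerAlphabet}.
#' @return a \linkS4class{RotamerAlphabet} with one state per amino acid.
#' @export
setGeneric("maskedAlphabet", function(x) standardGeneric("maskedAlphabet"))

#' Retrieve the alphabet of an object
#' @param x an object carrying a \linkS4class{RotamerAlphabet}.
#' @return the \linkS4class{RotamerAlphabet}.
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' Instantaneous rate matrix of a model
#' @param x a \linkS4class{RateModel}.
#' @return numeric matrix with zero row sums.
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' Equilibrium state frequencies of a model
#' @param x a \linkS4class{RateModel}.
#' @return numeric vector summing to 1.
#' @export
setGeneric("stateFreqs", function(x) standardGeneric("stateFreqs"))

#' Symmetric exchangeabilities of a reversible model
#' @param x a \linkS4class{RateModel}.
#' @return symmetric numeric matrix with \code{s_ij = q_ij / pi_j}.
#' @export
setGeneric("exchangeabilities", function(x) standardGeneric("exchangeabilities"))

#' Taxon labels of an alignment
#' @param x a \linkS4class{RotaAlignment}.
#' @return character vector.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Number of aligned sites
#' @param x a \linkS4class{RotaAlignment}.
#' @return integer scalar.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Integer state matrix of an alignment
#'
#' States are 1-based indices into the alphabet; 0 encodes a gap and -1 an
#' unknown/ambiguous state.
#' @param x a \linkS4class{RotaAlignment}.
#' @return integer matrix (taxa by sites).
#' @export
setGeneric("siteStates", function(x) standardGeneric("siteStates"))
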