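# Master single-character code table: states in fixed row order map onto
# this 55-symbol string; toy alphabets take a prefix.
MASTER_CHARS <- strsplit(
  "0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghijklmnopqrs", "")[[1]]

# Canonical residue table, in alphabetical three-letter order. chi1
# multiplicity: 1 for ALA/GLY (no side-chain chi1), 2 for PRO, 3 otherwise.
AA_TABLE <- data.frame(
  three = c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
            "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"),
  one   = c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V"),
  mult  = c(1L,3L,3L,3L,3L,3L,3L,1L,3L,3L,3L,3L,3L,3L,2L,3L,3L,3L,3L,3L),
  stringsAsFactors = FALSE)

.newAlphabet <- function(aa, rot, labels) {
  tokens <- paste0(aa, ifelse(is.na(rot), "-", rot))
  new("RotamerAlphabet", labels = labels, aa = aa, rot = rot,
      chars = MASTER_CHARS[seq_along(aa)], tokens = tokens)
}

#' The expanded 55-state amino-acid/chi1-rotamer alphabet
#'
#' States are ordered by amino acid (alphabetical three-letter code) and,
#' within each amino acid, by chi1 configuration index. Alanine and glycine
#' contribute one state each, proline two, and the remaining 17 residues
#' three, for 55 states in total. Configuration indices 1, 2 and 3
#' correspond to the chi1 wells near +60, -180 and -60 degrees (for proline,
#' 1 and 2 correspond to the wells near +27 and -25 degrees).
#'
#' @return a \linkS4class{RotamerAlphabet} with 55 states.
#' @examples
#' ab <- rotamerAlphabet()
#' nStates(ab)
#' @export
rotamerAlphabet <- function() {
  aa <- rep(AA_TABLE$one, AA_TABLE$mult)
  rot <- unlist(lapply(AA_TABLE$mult, function(m) if (m == 1L) NA_integer_ else seq_len(m)))
  three <- rep(AA_TABLE$three, AA_TABLE$mult)
  labels <- ifelse(is.na(rot), three, paste0(three, rot))
  .newAlphabet(aa, rot, labels)
}

#' A reduced expanded alphabet for testing and small examples
#'
#' Builds an alphabet of pseudo-amino-acids with the given chi1 rotamer
#' multiplicities, mirroring the structure of the full 55-state set at a
#' size where brute-force oracles remain tractable.
#'
#' @param multiplicities integer vector with values in 1..3, one entry per
#'   pseudo-amino-acid.
#' @param aa one-letter codes for the pseudo-amino-acids.
#' @return a \linkS4class{RotamerAlphabet}.
#' @examples
#' toyAlphabet(c(3, 3, 2, 1))
#' @export
toyAlphabet <- function(multiplicities, aa = LETTERS[seq_along(multiplicities)]) {
  multiplicities <- as.integer(multiplicities)
  if (any(!multiplicities %in% 1:3)) stop("multiplicities must be in 1..3")
  if (length(aa) != length(multiplicities) || anyDuplicated(aa))
    stop("need one distinct letter per pseudo-amino-acid")
  aav <- rep(aa, multiplicities)
  rot <- unlist(lapply(multiplicities, function(m) if (m == 1L) NA_integer_ else seq_len(m)))
  labels <- paste0(aav, ifelse(is.na(rot), "", rot))
  .newAlphabet(aav, rot, labels)
}

#' @describeIn rotamerAlphabet number of states
#' @param x alphabet
#' @export
setMethod("nStates", "RotamerAlphabet", function(x) length(x@labels))

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "RotamerAlphabet", function(x) x@labels)

#' @rdname stateTokens
#' @export
setMethod("stateTokens", "RotamerAlphabet", function(x) x@tokens)

#' @rdname stateChars
#' @export
setMethod("stateChars", "RotamerAlphabet", function(x) x@chars)

#' @rdname aminoAcids
#' @export
setMethod("aminoAcids", "RotamerAlphabet", function(x) x@aa)

#' @rdname rotamerIndices
#' @export
setMethod("rotamerIndices", "RotamerAlphabet", function(x) x@rot)

#' @rdname aaLevels
#' @export
setMethod("aaLevels", "RotamerAlphabet", function(x) unique(x@aa))

#' @rdname maskedAlphabet
#' @export
setMethod("maskedAlphabet", "RotamerAlphabet", function(x) {
  lev <- unique(x@aa)
  if (length(lev) == length(x@aa)) return(x)  # already one state per residue
  first <- match(lev, x@aa)
  lab <- sub("[0-9]$", "", x@labels[first])
  tokens <- paste0(lev, "-")
  new("RotamerAlphabet", labels = lab, aa = lev,
      rot = rep(NA_integer_, length(lev)), chars = lev, tokens = tokens)
})

setMethod("show", "RotamerAlphabet", function(object) {
  cat("RotamerAlphabet with", length(object@labels), "states over",
      length(unique(object@aa)), "amino acids\n")
  cat("  ", paste(utils::head(object@labels, 8), collapse = " "),
      if (length(object@labels) > 8) "..." else "", "\n")
})

#' Map each expanded state to its amino-acid state index
#'
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @return integer vector: for state i, the index of its amino acid in
#'   \code{maskedAlphabet(alphabet)}.
#' @export
maskIndex <- function(alphabet) match(alphabet@aa, unique(alphabet@aa))

#' Per-amino-acid rotamer multiplicities |R_A|
#'
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @return named integer vector over \code{aaLevels(alphabet)}.
#' @export
rotamerMultiplicity <- function(alphabet) {
  tab <- table(factor(alphabet@aa, levels = unique(alphabet@aa)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Resolve state labels or tokens to state indices
#'
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @param x character vector of labels (\code{"ARG1"}) or tokens
#'   (\code{"R1"}); gap \code{"-"} and unknown \code{"?"} map to their codes.
#' @return integer vector of indices (gap = 0, unknown = -1).
#' @export
stateIndex <- function(alphabet, x) {
  i <- match(x, alphabet@labels)
  j <- match(x, alphabet@tokens)
  i[is.na(i)] <- j[is.na(i)]
  i[x == GAP_CHAR] <- GAP_CODE
  i[x == UNK_CHAR] <- UNK_CODE
  if (anyNA(i))
    stop("unknown state symbol(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  as.integer(i)
}

# --- encode/decode between integer codes and character dialects ----------

.codesToChars <- function(alphabet, codes) {
  out <- character(length(codes))
  out[codes > 0L] <- alphabet@chars[codes[codes > 0L]]
  out[codes == GAP_CODE] <- GAP_CHAR
  out[codes == UNK_CODE] <- UNK_CHAR
  out
}

.charsToCodes <- function(alphabet, chars, what = "sequence") {
  i <- match(chars, alphabet@chars)
  i[chars == GAP_CHAR] <- GAP_CODE
  i[chars == UNK_CHAR] <- UNK_CODE
  if (anyNA(i)) {
    pos <- which(is.na(i))[1]
    stop("invalid symbol '", chars[pos], "' at position ", pos, " in ", what)
  }
  as.integer(i)
}

#' Encode integer state codes as a single-character string
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @param codes integer state codes (0 gap, -1 unknown).
#' @return character scalar.
#' @export
encodeChars <- function(alphabet, codes) paste(.codesToChars(alphabet, codes), collapse = "")

#' Decode a single-character string to integer state codes
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @param string character scalar in the single-character dialect.
#' @return integer vector of state codes.
#' @export
decodeChars <- function(alphabet, string) .charsToCodes(alphabet, strsplit(string, "")[[1]])

#' Encode integer state codes as whitespace-separated two-token codes
#' @inheritParams encodeChars
#' @return character scalar, tokens separated by single spaces.
#' @export
encodeTokens <- function(alphabet, codes) {
  out <- character(length(codes))
  out[codes > 0L] <- alphabet@tokens[codes[codes > 0L]]
  out[codes == GAP_CODE] <- GAP_CHAR
  out[codes == UNK_CODE] <- UNK_CHAR
  paste(out, collapse = " ")
}

#' Decode whitespace-separated two-token codes to integer state codes
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @param string character scalar in the two-token dialect.
#' @return integer vector of state codes.
#' @export
decodeTokens <- function(alphabet, string) {
  toks <- strsplit(trimws(string), "[[:space:]]+")[[1]]
  i <- match(toks, alphabet@tokens)
  i[toks == GAP_CHAR] <- GAP_CODE
  i[toks == UNK_CHAR] <- UNK_CODE
  if (anyNA(i)) {
    pos <- which(is.na(i))[1]
    stop("invalid state token '", toks[pos], "' at position ", pos)
  }
  as.integer(i)
}

# --- alignment container --------------------------------------------------

#' Construct a RotaAlignment
#'
#' @param states integer matrix of state codes (taxa by sites, rows named),
#'   or a character matrix of labels/tokens.
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @return a \linkS4class{RotaAlignment}.
#' @export
rotaAlignment <- function(states, alphabet) {
  if (is.character(states)) {
    m <- matrix(stateIndex(alphabet, states), nrow = nrow(states),
                dimnames = dimnames(states))
    states <- m
  }
  storage.mode(states) <- "integer"
  new("RotaAlignment", states = states, alphabet = alphabet)
}

#' @rdname taxa
#' @export
setMethod("taxa", "RotaAlignment", function(x) rownames(x@states))

#' @rdname nSites
#' @export
setMethod("nSites", "RotaAlignment", function(x) ncol(x@states))

#' @rdname siteStates
#' @export
setMethod("siteStates", "RotaAlignment", function(x) x@states)

#' @rdname alphabet
#' @export
setMethod("alphabet", "RotaAlignment", function(x) x@alphabet)

#' @rdname nStates
#' @export
setMethod("nStates", "RotaAlignment", function(x) length(x@alphabet@labels))

setMethod("show", "RotaAlignment", function(object) {
  cat("RotaAlignment:", nrow(object@states), "taxa x", ncol(object@states),
      "sites over", length(object@alphabet@labels), "states\n")
})

#' Mask the rotamer component of a rotasequence or alignment
#'
#' Maps every (amino acid, rotamer) state to its amino-acid state, i.e.
#' (A,R) -> A, preserving gaps and unknowns. Applied to an alignment that is
#' already amino-acid-level, this is the identity.
#'
#' @param x a \linkS4class{RotaAlignment}, or an integer vector of state
#'   codes (in which case \code{alphabet} must be given).
#' @param alphabet alphabet for vector input.
#' @return object of the same kind over \code{maskedAlphabet(alphabet)}.
#' @export
maskRotamers <- function(x, alphabet = NULL) {
  if (is(x, "RotaAlignment")) {
    ab <- x@alphabet
    map <- maskIndex(ab)
    m <- x@states
    pos <- m > 0L
    m[pos] <- map[m[pos]]
    return(new("RotaAlignment", states = m, alphabet = maskedAlphabet(ab)))
  }
  if (is.null(alphabet)) stop("alphabet required for vector input")
  map <- maskIndex(alphabet)
  out <- x
  out[x > 0L] <- map[x[x > 0L]]
  out
}
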