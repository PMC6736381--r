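# chi1 rotamer assignment from atomic coordinates.
#
# chi1 is the dihedral about the CA-CB bond, defined by N, CA, CB and a
# fourth atom that depends on the residue: CG for most side-chains, OG for
# serine, OG1 for threonine, CG1 for isoleucine and valine, SG for cysteine.
# Three wells (~+60, ~-180, ~-60 degrees) are indexed 1, 2, 3; proline has
# two accessible wells (~+27, ~-25) indexed 1, 2.

CHI1_FOURTH_ATOM <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1")

#' Atoms defining chi1 for a residue
#' @param resname three-letter residue code.
#' @return character vector \code{c("N","CA","CB",<fourth>)}, or \code{NULL}
#'   for ALA/GLY (no chi1).
#' @export
chi1Atoms <- function(resname) {
  if (resname %in% c("ALA", "GLY")) return(NULL)
  fourth <- CHI1_FOURTH_ATOM[[resname]]
  if (is.null(fourth)) stop("nonstandard residue: ", resname)
  c("N", "CA", "CB", fourth)
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: the angle of p4 relative to p1 viewed along
#' the p2 -> p3 axis, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2]*b2[3] - b1[3]*b2[2], b1[3]*b2[1] - b1[1]*b2[3],
          b1[1]*b2[2] - b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3] - b2[3]*b3[2], b2[3]*b3[1] - b2[1]*b3[3],
          b2[1]*b3[2] - b2[2]*b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate geometry: collinear points in dihedral computation")
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2]*b2n[3] - n1[3]*b2n[2], n1[3]*b2n[1] - n1[1]*b2n[3],
          n1[1]*b2n[2] - n1[2]*b2n[1])
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Assign a chi1 rotamer configuration index from a dihedral angle
#'
#' Non-proline residues use equidistant boundaries between the three wells:
#' angles in [0, 120) map to configuration 1 (gauche+, ~60), [120, 180] and
#' [-180, -120) to configuration 2 (trans, ~-180), and [-120, 0) to
#' configuration 3 (gauche-, ~-60). Proline maps nonnegative chi1 to 1
#' (~+27) and negative to 2 (~-25). Angles are first wrapped to
#' (-180, 180].
#'
#' @param resname three-letter residue code (not ALA/GLY).
#' @param chi1 dihedral angle in degrees.
#' @return integer configuration index.
#' @export
assignRotamer <- function(resname, chi1) {
  if (resname %in% c("ALA", "GLY"))
    stop(resname, " has no chi1 rotamer configuration")
  if (!resname %in% names(CHI1_FOURTH_ATOM))
    stop("nonstandard residue: ", resname)
  a <- ((chi1 + 180) %% 360) - 180          # wrap to [-180, 180)
  if (a == -180) a <- 180
  if (resname == "PRO") return(if (a >= 0) 1L else 2L)
  if (a >= 0 && a < 120) 1L
  else if (a >= 120 || a < -120) 2L
  else 3L
}

#' Quality filter for a residue record
#'
#' A residue is dropped when the mean B-factor of its four chi1-defining
#' atoms exceeds \code{bMax}, when its peptide bond to the next residue
#' exceeds \code{bondMax} (a chain break), when it is a nonstandard residue,
#' or when it is disordered (chi1 atoms missing or at zero occupancy).
#' ALA/GLY have no chi1 atoms and are exempt from the B-factor and
#' missing-atom checks.
#'
#' @param resname three-letter residue code.
#' @param bFactors B-factors of the chi1-defining atoms.
#' @param bondToNext peptide C-N bond length to the next residue (Angstrom),
#'   or \code{NA} for the chain terminus.
#' @param hasAtoms are all chi1-defining atoms present?
#' @param zeroOccupancy is any chi1-defining atom at zero occupancy?
#' @param bMax B-factor threshold (default 30).
#' @param bondMax chain-break threshold in Angstrom (default 1.8).
#' @return list with logical \code{keep} and a \code{reason} code
#'   (\code{"ok"}, \code{"nonstandard"}, \code{"disordered"},
#'   \code{"b_factor"}, \code{"chain_break"}).
#' @export
filterResidue <- function(resname, bFactors = numeric(), bondToNext = NA,
                          hasAtoms = TRUE, zeroOccupancy = FALSE,
                          bMax = 30, bondMax = 1.8) {
  drop <- function(reason) list(keep = FALSE, reason = reason)
  if (!resname %in% AA_TABLE$three) return(drop("nonstandard"))
  chi <- !resname %in% c("ALA", "GLY")
  if (chi && (!hasAtoms || zeroOccupancy)) return(drop("disordered"))
  if (chi && length(bFactors) && mean(bFactors) > bMax) return(drop("b_factor"))
  if (!is.na(bondToNext) && bondToNext > bondMax) return(drop("chain_break"))
  list(keep = TRUE, reason = "ok")
}

#' Read residue atom records from a PDB or mmCIF file
#'
#' Thin wrapper over \pkg{bio3d}'s parsers returning a long atom table.
#' Only ATOM records are kept; for alternate locations the highest-occupancy
#' conformer is retained.
#'
#' @param path coordinate file (\code{.pdb} or \code{.cif}).
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{x}, \code{y}, \code{z}, \code{b},
#'   \code{occ}.
#' @export
readStructureResidues <- function(path) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  df <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                   atom = at$elety, x = at$x, y = at$y, z = at$z,
                   b = at$b, occ = at$o, stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  # keep highest-occupancy conformer per (chain, resno, atom)
  o <- order(df$chain, df$resno, df$atom, -df$occ)
  df <- df[o, , drop = FALSE]
  key <- paste(df$chain, df$resno, df$atom, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df[order(df$chain, df$resno), , drop = FALSE]
}

.atomCoord <- function(res, name) {
  i <- match(name, res$atom)
  if (is.na(i)) return(NULL)
  c(res$x[i], res$y[i], res$z[i])
}

#' Convert one chain of residue records into a rotasequence
#'
#' Computes chi1 for every residue with a side-chain, assigns rotamer
#' configurations, and applies the quality filters. Filtered residues emit
#' the UNKNOWN state so the sequence frame is preserved; ALA and GLY emit
#' their single state.
#'
#' @param atoms atom table as returned by \code{\link{readStructureResidues}}
#'   or \code{\link{toyStructure}}.
#' @param chain chain identifier; default takes the first chain present.
#' @param bMax,bondMax filter thresholds (see \code{\link{filterResidue}}).
#' @param alphabet target \linkS4class{RotamerAlphabet} (default the full
#'   55-state alphabet).
#' @return list with \code{states} (integer codes), \code{tokens}
#'   (character) and a per-residue \code{report} data.frame (resno, resname,
#'   chi1, rotamer, keep, reason).
#' @export
structureToRotasequence <- function(atoms, chain = NULL, bMax = 30,
                                    bondMax = 1.8,
                                    alphabet = rotamerAlphabet()) {
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  resnos <- unique(atoms$resno)
  if (!length(resnos)) stop("empty chain: ", chain)
  resnos <- sort(resnos)
  n <- length(resnos)
  states <- integer(n)
  rep <- data.frame(resno = resnos, resname = NA_character_,
                    chi1 = NA_real_, rotamer = NA_integer_,
                    keep = NA, reason = NA_character_)
  three2one <- stats::setNames(AA_TABLE$one, AA_TABLE$three)
  for (i in seq_len(n)) {
    res <- atoms[atoms$resno == resnos[i], , drop = FALSE]
    resname <- res$resname[1]
    rep$resname[i] <- resname
    # peptide bond C(i) - N(i+1)
    bond <- NA_real_
    if (i < n) {
      nxt <- atoms[atoms$resno == resnos[i + 1L], , drop = FALSE]
      cc <- .atomCoord(res, "C"); nn <- .atomCoord(nxt, "N")
      if (!is.null(cc) && !is.null(nn)) bond <- sqrt(sum((cc - nn)^2))
    }
    std <- resname %in% AA_TABLE$three
    chiAtoms <- if (std) chi1Atoms(resname) else NULL
    coords <- lapply(chiAtoms, .atomCoord, res = res)
    hasAtoms <- is.null(chiAtoms) || !any(vapply(coords, is.null, TRUE))
    bf <- if (!is.null(chiAtoms) && hasAtoms)
      res$b[match(chiAtoms, res$atom)] else numeric()
    occ0 <- if (!is.null(chiAtoms) && hasAtoms)
      any(res$occ[match(chiAtoms, res$atom)] <= 0) else FALSE
    dec <- filterResidue(resname, bFactors = bf, bondToNext = bond,
                         hasAtoms = hasAtoms, zeroOccupancy = occ0,
                         bMax = bMax, bondMax = bondMax)
    rep$keep[i] <- dec$keep
    rep$reason[i] <- dec$reason
    if (!dec$keep) { states[i] <- UNK_CODE; next }
    if (is.null(chiAtoms)) {
      states[i] <- which(alphabet@aa == three2one[[resname]] &
                           is.na(alphabet@rot))
    } else {
      chi <- dihedralAngle(coords[[1]], coords[[2]], coords[[3]], coords[[4]])
      rot <- assignRotamer(resname, chi)
      rep$chi1[i] <- chi
      rep$rotamer[i] <- rot
      states[i] <- which(alphabet@aa == three2one[[resname]] &
                           !is.na(alphabet@rot) & alphabet@rot == rot)
    }
  }
  tokens <- ifelse(states > 0L, alphabet@tokens[pmax(states, 1L)],
                   ifelse(states == GAP_CODE, GAP_CHAR, UNK_CHAR))
  list(states = states, tokens = tokens, report = rep)
}
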