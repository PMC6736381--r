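# Synthetic generators: toy expanded-alphabet models, ideal-geometry
# coordinate sets realizing prescribed chi1 angles, simulated families with
# ground-truth bookkeeping, and torsion-angle samples. Everything is
# reproducible from an explicit seed and exercises the full pipeline
# without any external data.

#' Random expanded-alphabet model with its correctly lumped counterpart
#'
#' Draws strictly positive symmetric substitution counts over a (toy or
#' full) expanded alphabet with a conservation-dominant diagonal, runs the
#' estimation pipeline to a superscaled reversible model, and also builds
#' the amino-acid-level model from the lumped (merged submatrix) counts.
#'
#' @param multiplicities rotamer multiplicities of the pseudo-amino-acids
#'   (ignored when \code{alphabet} is supplied).
#' @param seed RNG seed.
#' @param alphabet optional \linkS4class{RotamerAlphabet} (e.g.
#'   \code{rotamerAlphabet()} for a random full-size 55-state model).
#' @param diagBoost factor by which diagonal (conservation) counts exceed
#'   typical off-diagonal counts; conservation dominates real data.
#' @return list with \code{model}, \code{lumped} (amino-acid model),
#'   \code{counts}, \code{counts20}, \code{alphabet}, \code{alphabet20}.
#' @export
toyModel <- function(multiplicities = c(3, 3, 2, 1), seed = 1,
                     alphabet = NULL, diagBoost = 10) {
  if (is.null(alphabet)) alphabet <- toyAlphabet(multiplicities)
  set.seed(seed)
  n <- length(alphabet@labels)
  M <- matrix(stats::runif(n * n, 0.2, 5), n, n)
  N <- (M + t(M)) * 10
  diag(N) <- diag(N) * diagBoost
  dimnames(N) <- list(alphabet@labels, alphabet@labels)
  ab20 <- maskedAlphabet(alphabet)
  N20 <- lumpCounts(N, alphabet)
  list(model = countsToRateModel(N, alphabet),
       lumped = countsToRateModel(N20, ab20),
       counts = N, counts20 = N20,
       alphabet = alphabet, alphabet20 = ab20)
}

# place a fourth atom at given bond length, bond angle (deg) and dihedral
# (deg) relative to three anchor points (standard internal-coordinate
# construction).
.placeAtom <- function(p1, p2, p3, length, angle, dihedral) {
  b1 <- p2 - p1; b2 <- p3 - p2
  b2n <- b2 / sqrt(sum(b2^2))
  nrm <- c(b1[2]*b2[3] - b1[3]*b2[2], b1[3]*b2[1] - b1[1]*b2[3],
           b1[1]*b2[2] - b1[2]*b2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(nrm[2]*b2n[3] - nrm[3]*b2n[2], nrm[3]*b2n[1] - nrm[1]*b2n[3],
         nrm[1]*b2n[2] - nrm[2]*b2n[1])
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  d <- length * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  p3 + d[1] * b2n + d[2] * m + d[3] * nrm
}

#' Ideal-geometry chain realizing prescribed chi1 angles
#'
#' Builds an extended backbone (N, CA, C per residue, CB and the
#' chi1-defining fourth atom where applicable) in which each residue's chi1
#' dihedral equals its prescribed target. B-factors and the peptide-bond
#' length to the next residue can be overridden per residue to exercise the
#' quality filters.
#'
#' @param sequence character vector of three-letter residue codes.
#' @param chi1 numeric vector of target chi1 angles in degrees; entries for
#'   ALA/GLY must be NA.
#' @param bFactors scalar or per-residue B-factor (default 10).
#' @param bondNext scalar or per-residue C-N(next) bond length in Angstrom
#'   (default 1.33; values > 1.8 trigger the chain-break filter).
#' @param chain chain identifier.
#' @return atom table compatible with
#'   \code{\link{structureToRotasequence}}.
#' @export
toyStructure <- function(sequence, chi1, bFactors = 10, bondNext = 1.33,
                         chain = "A") {
  nres <- length(sequence)
  if (length(chi1) != nres) stop("chi1 targets must match sequence length")
  bFactors <- rep_len(bFactors, nres)
  bondNext <- rep_len(bondNext, nres)
  bad <- sequence %in% c("ALA", "GLY") & !is.na(chi1)
  if (any(bad))
    stop("chi1 target given for residue without chi1: ",
         paste(unique(sequence[bad]), collapse = ", "))
  rows <- list()
  spacing <- 3.8
  cPrev <- NULL
  origin <- c(0, 0, 0)
  for (i in seq_len(nres)) {
    res <- sequence[i]
    # place N so the previous C-N bond has the requested length
    N <- if (is.null(cPrev)) origin else cPrev + c(bondNext[i - 1L], 0, 0)
    CA <- N + c(1.45, 0, 0)
    C <- CA + c(1.05, 0, 0)
    cPrev <- C
    atoms <- data.frame(atom = c("N", "CA", "C"),
                        x = c(N[1], CA[1], C[1]),
                        y = c(N[2], CA[2], C[2]),
                        z = c(N[3], CA[3], C[3]))
    if (res != "GLY") {
      CB <- CA + 1.53 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
      atoms <- rbind(atoms, data.frame(atom = "CB", x = CB[1], y = CB[2],
                                       z = CB[3]))
      if (!res %in% c("ALA")) {
        fourth <- chi1Atoms(res)[4]
        X <- .placeAtom(N, CA, CB, 1.52, 111, chi1[i])
        atoms <- rbind(atoms, data.frame(atom = fourth, x = X[1], y = X[2],
                                         z = X[3]))
      }
    }
    atoms$chain <- chain; atoms$resno <- i; atoms$resname <- res
    atoms$b <- bFactors[i]; atoms$occ <- 1
    rows[[i]] <- atoms
  }
  df <- do.call(rbind, rows)
  df[, c("chain", "resno", "resname", "atom", "x", "y", "z", "b", "occ")]
}

#' Write an atom table as a minimal PDB file
#'
#' @param atoms atom table (as from \code{\link{toyStructure}}).
#' @param path output path.
#' @export
writeStructurePDB <- function(atoms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    el <- substr(gsub("[0-9]", "", a$atom), 1, 1)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$atom, a$resname, a$chain, a$resno, a$x, a$y, a$z, a$occ, a$b, el),
      con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Simulated family with ground-truth bookkeeping
#'
#' Simulates an alignment (recording ancestral sequences) and tallies the
#' true per-branch endpoint differences into a symmetric count matrix, so
#' the counting and reconstruction modules can be checked against planted
#' truth.
#'
#' @inheritParams simulateAlignment
#' @return list with \code{alignment}, \code{internal}, \code{trueCounts}
#'   (symmetric tally over branches of endpoint state pairs) and
#'   \code{tree}.
#' @export
plantedFamily <- function(tree, model, nSites, seed = NULL) {
  sim <- simulateAlignment(tree, model, nSites, seed = seed,
                           recordInternal = TRUE)
  n <- length(model@pi)
  ntip <- length(tree$tip.label)
  all <- rbind(sim$alignment@states, sim$internal@states)
  rownames(all) <- c(tree$tip.label,
                     paste0("node", (ntip + 1L):(ntip + tree$Nnode)))
  idOf <- function(i) if (i <= ntip) tree$tip.label[i] else paste0("node", i)
  M <- matrix(0, n, n, dimnames = list(model@alphabet@labels,
                                       model@alphabet@labels))
  for (k in seq_len(nrow(tree$edge))) {
    a <- all[idOf(tree$edge[k, 1]), ]
    b <- all[idOf(tree$edge[k, 2]), ]
    for (s in seq_len(nSites)) {
      M[a[s], b[s]] <- M[a[s], b[s]] + 1
      M[b[s], a[s]] <- M[b[s], a[s]] + 1
    }
  }
  list(alignment = sim$alignment, internal = sim$internal, trueCounts = M,
       tree = tree)
}

#' Periodic (phi, psi) samples from a mixture of wrapped components
#'
#' Draws angle pairs from a mixture of isotropic wrapped-normal components,
#' for feeding the Ramachandran-overlap machinery with known ground truth.
#'
#' @param means k x 2 matrix of component means (degrees).
#' @param sds scalar or length-k angular standard deviation (degrees).
#' @param weights mixture weights (default equal).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return data.frame with columns \code{phi}, \code{psi}.
#' @export
torsionSamples <- function(means, sds = 15, weights = NULL, n = 1000,
                           seed = NULL) {
  means <- rbind(means)
  k <- nrow(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0)
    stop("invalid mixture weights")
  weights <- weights / sum(weights)
  sds <- rep_len(sds, k)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  wrap <- function(a) { a <- ((a + 180) %% 360) - 180; a[a == -180] <- 180; a }
  data.frame(phi = wrap(stats::rnorm(n, means[comp, 1], sds[comp])),
             psi = wrap(stats::rnorm(n, means[comp, 2], sds[comp])))
}
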