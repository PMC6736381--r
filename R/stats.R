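# Exchange-pattern analysis of a normalized count (or rate) matrix: per
# amino-acid-pair chi-squared independence tests with Bonferroni
# correction, bias-corrected Cramer's V, diagonal ratios, biochemical
# grouping, Ramachandran-density overlaps and overlap/exchangeability rank
# correlations.

BIOCHEMICAL_GROUPS <- list(
  aliphatic = c("I", "L", "V"), aromatic = c("F", "W", "Y"),
  positive = c("R", "K", "H"), carboxylamine = c("N", "Q"),
  negative = c("D", "E"), hydroxyl = c("S", "T"))

#' Biochemical group of an amino acid
#' @param aa one-letter code(s).
#' @return group name, or NA for residues outside the six groups
#'   (methionine is deliberately ungrouped).
#' @export
biochemicalGroup <- function(aa) {
  lut <- unlist(lapply(names(BIOCHEMICAL_GROUPS), function(g)
    stats::setNames(rep(g, length(BIOCHEMICAL_GROUPS[[g]])),
                    BIOCHEMICAL_GROUPS[[g]])))
  unname(lut[aa])
}

.chisqIndep <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  ok <- e > 0
  x2 <- sum((tab[ok] - e[ok])^2 / e[ok])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = x2, df = df,
       p = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Bias-corrected Cramer's V
#'
#' Bergsma's correction: \code{phi2~ = max(0, X2/n - (r-1)(c-1)/(n-1))},
#' with similarly shrunk row/column counts, and \code{V~ =
#' sqrt(phi2~ / min(r~-1, c~-1))}.
#'
#' @param tab two-dimensional contingency table (counts may be
#'   non-integer).
#' @return V in [0, 1]; NA for degenerate (single row/column) tables.
#' @export
cramersVCorrected <- function(tab) {
  r <- nrow(tab); cc <- ncol(tab); n <- sum(tab)
  if (r < 2 || cc < 2 || n <= 1) return(NA_real_)
  phi2 <- .chisqIndep(tab)$statistic / n
  phi2c <- max(0, phi2 - (r - 1) * (cc - 1) / (n - 1))
  rc <- r - (r - 1)^2 / (n - 1)
  ccc <- cc - (cc - 1)^2 / (n - 1)
  denom <- min(rc - 1, ccc - 1)
  if (denom <= 0) return(NA_real_)
  sqrt(phi2c / denom)
}

#' Proportion of a square table's total on its diagonal
#' @param tab square numeric matrix with positive total.
#' @return trace/total in [0, 1]; NA for non-square or zero-total tables.
#' @export
diagonalRatio <- function(tab) {
  if (nrow(tab) != ncol(tab)) return(NA_real_)
  tot <- sum(tab)
  if (tot <= 0) return(NA_real_)
  sum(diag(tab)) / tot
}

#' Rotamer-configuration association tests for all amino-acid pairs
#'
#' For every unordered pair of different amino acids that both have at
#' least two rotamer configurations, tests the off-diagonal submatrix of
#' the (normalized) count matrix for independence of the two residues'
#' chi1 configurations (Pearson chi-squared with expected counts from the
#' marginals), applies a Bonferroni correction over the testable pairs, and
#' reports the bias-corrected Cramer's V, the diagonal ratio (square
#' submatrices only) and the biochemical group pair.
#'
#' @param nhat symmetric (normalized) count matrix in alphabet state order.
#' @param alphabet the \linkS4class{RotamerAlphabet}.
#' @param nTests number of tests for the Bonferroni correction; defaults to
#'   the number of testable pairs.
#' @return data.frame with one row per pair: aa1, aa2, rows, cols,
#'   statistic, df, p, pBonferroni, cramersV, diagonalRatio, group1,
#'   group2, testable.
#' @export
submatrixTests <- function(nhat, alphabet, nTests = NULL) {
  lev <- unique(alphabet@aa)
  mult <- rotamerMultiplicity(alphabet)
  idx <- split(seq_along(alphabet@aa), factor(alphabet@aa, levels = lev))
  multi <- lev[mult[lev] >= 2]
  out <- list()
  for (i in seq_along(multi)) for (j in seq_along(multi)) {
    if (j <= i) next
    a <- multi[i]; b <- multi[j]
    tab <- nhat[idx[[a]], idx[[b]], drop = FALSE]
    testable <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    ch <- if (testable) .chisqIndep(tab) else
      list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      aa1 = a, aa2 = b, rows = nrow(tab), cols = ncol(tab),
      statistic = ch$statistic, df = ch$df, p = ch$p,
      cramersV = if (testable) cramersVCorrected(tab) else NA_real_,
      diagonalRatio = diagonalRatio(tab),
      group1 = biochemicalGroup(a), group2 = biochemicalGroup(b),
      testable = testable)
  }
  res <- do.call(rbind, out)
  if (is.null(nTests)) nTests <- sum(res$testable)
  res$pBonferroni <- pmin(1, res$p * nTests)
  res
}

#' Periodic torsion-angle density on a regular grid
#'
#' Histogram density of (phi, psi) samples on a bins x bins grid over
#' (-180, 180]^2 with periodic wrapping; cell probabilities sum to 1.
#'
#' @param phi,psi angle samples in degrees.
#' @param bins grid resolution per axis (default 72, i.e. 5-degree cells).
#' @return bins x bins matrix of cell probabilities (class kept plain);
#'   attribute \code{"bins"} records the resolution.
#' @export
torsionDensity <- function(phi, psi, bins = 72L) {
  if (length(phi) != length(psi)) stop("phi and psi lengths differ")
  wrap <- function(a) {
    a <- ((a + 180) %% 360) - 180
    a[a == -180] <- 180
    a
  }
  cut0 <- function(a) pmin(bins, 1L + floor((wrap(a) + 180) / (360 / bins)))
  tab <- table(factor(cut0(phi), levels = seq_len(bins)),
               factor(cut0(psi), levels = seq_len(bins)))
  m <- as.matrix(tab) / length(phi)
  attr(m, "bins") <- bins
  m
}

#' Ramachandran overlap of two torsion densities
#'
#' The integral of the pointwise minimum of two (phi, psi) probability
#' densities, evaluated on their common grid: 1 for identical densities, 0
#' for disjoint supports.
#'
#' @param f,g torsion-density matrices from \code{\link{torsionDensity}}
#'   (same grid size).
#' @return overlap in [0, 1].
#' @export
ramachandranOverlap <- function(f, g) {
  if (!all(dim(f) == dim(g))) stop("densities are on different grids")
  sum(pmin(f, g))
}

#' Rank correlation between Ramachandran overlaps and exchangeabilities
#'
#' Spearman correlation (average ranks for ties) between the off-diagonal
#' exchangeabilities of rotamer-state pairs and their backbone-distribution
#' overlaps. \code{scope = "global"} pools all supplied pairs;
#' \code{scope = "perPair"} computes one correlation per amino-acid pair
#' submatrix and reports the fraction with positive rho.
#'
#' @param S exchangeability matrix in alphabet state order.
#' @param O overlap matrix in the same order.
#' @param alphabet the \linkS4class{RotamerAlphabet}.
#' @param scope \code{"global"} or \code{"perPair"}.
#' @return for \code{"global"}: list(rho, p, n). For \code{"perPair"}: list
#'   with a per-pair data.frame and \code{fracPositive}.
#' @export
overlapExchangeabilityCorrelation <- function(S, O, alphabet,
                                              scope = c("global", "perPair")) {
  scope <- match.arg(scope)
  aa <- alphabet@aa
  differ <- outer(aa, aa, "!=") & upper.tri(S)
  if (scope == "global") {
    ct <- suppressWarnings(
      stats::cor.test(S[differ], O[differ], method = "spearman"))
    return(list(rho = unname(ct$estimate), p = ct$p.value,
                n = sum(differ)))
  }
  lev <- unique(aa)
  mult <- rotamerMultiplicity(alphabet)
  idx <- split(seq_along(aa), factor(aa, levels = lev))
  multi <- lev[mult[lev] >= 2]
  rows <- list()
  for (i in seq_along(multi)) for (j in seq_along(multi)) {
    if (j <= i) next
    a <- multi[i]; b <- multi[j]
    s <- as.vector(S[idx[[a]], idx[[b]]])
    o <- as.vector(O[idx[[a]], idx[[b]]])
    if (length(s) < 3 || length(unique(s)) < 2 || length(unique(o)) < 2) {
      rows[[length(rows) + 1L]] <- data.frame(aa1 = a, aa2 = b,
                                              rho = NA_real_, n = length(s))
      next
    }
    rho <- suppressWarnings(stats::cor(s, o, method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(aa1 = a, aa2 = b, rho = rho,
                                            n = length(s))
  }
  df <- do.call(rbind, rows)
  list(perPair = df, fracPositive = mean(df$rho > 0, na.rm = TRUE))
}
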