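---
title: "Rotamer-aware substitution models: methods and design"
author: "rotasub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotamer-aware substitution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotasub)
```

## The model

Classical empirical amino-acid substitution models describe protein
evolution as a reversible continuous-time Markov chain on 20 states. This
package implements the same machinery on an expanded alphabet in which each
residue is paired with the discrete conformation of its first side-chain
dihedral angle, chi1. Chi1 connects two sp3 atoms and is strictly rotameric:
for most residues it occupies one of three wells near +60, -180 and -60
degrees (indexed 1, 2, 3); proline's pyrrolidine ring leaves only two
accessible wells (near +27 and -25 degrees); alanine and glycine have no
chi1. That yields 17 x 3 + 2 + 2 x 1 = 55 states. A protein with known
structure becomes a "rotasequence" over this alphabet, and substitution
processes on it capture both amino-acid replacement and side-chain
reorientation.

The estimation pipeline is deliberately "Dayhoff-like" (count-based, not
ML over alignments):

1. **Counting.** Aligned rotasequence pairs are chosen by a circular tour
   through a neighbor-joining tree of each family, so every sequence enters
   exactly two comparisons and each observed difference is counted at most
   twice. Pairs under 75% rotasequence identity are skipped to limit
   multiple-hit bias. An observed i/j difference adds 1 to both `n_ij` and
   `n_ji`; a conserved site adds 2 to `n_ii`, so row sums count all
   observations of each state.
2. **Normalization.** Structure-quality filtering (B-factors, chain breaks,
   disorder) biases residue composition — alanine and glycine can never be
   B-factor-filtered, for example. Each (A, A') rotamer submatrix of the
   expanded counts is therefore rescaled to sum to the amino-acid-level
   count `n_AA'` obtained without B-factor filtering, recovering the
   observed residue frequencies while preserving within-submatrix rotamer
   exchange patterns.
3. **Rates.** The rate of i -> j is the count `n_ij` as a proportion of all
   observations of i (conserved sites included); frequencies are row sums.
   Symmetric counts make the chain reversible by construction.
4. **Scaling.** Rates are first scaled so one unit of time produces one
   expected state substitution at equilibrium (constant `rho`), then
   "superscaled" by `rho*`, the equilibrium proportion of substitutions
   that change the amino acid. In superscaled units one time unit is one
   expected amino-acid change, making branch lengths directly comparable
   with 20-state models; the process also performs `(1-rho*)/rho*`
   pure-rotamer events per unit time that 20-state models cannot see.
5. **Exchangeabilities.** `s_ij = q_ij / pi_j` gives the symmetric
   exchangeability matrix stored in model files; combining it with
   frequencies from another data set (`q_ij = s_ij pi'_j`) is the standard
   "+F" parametrization.

Likelihoods use Felsenstein pruning with the usual site-independence
assumption, gaps/unknowns as total ambiguity, per-node rescaling, and
transition probabilities from the symmetric eigendecomposition available
for reversible models (`B = D Q D^-1` with `D = diag(sqrt(pi))`). Rate
heterogeneity uses the discretized gamma with equal-probability categories
represented by their means (4 categories by default). Ancestral states are
reconstructed marginally (up/down message passing; posteriors per node and
site) or jointly (max-product dynamic programming with traceback, ties
broken toward the lowest state index).

## Chi1 assignment and quality filters

Chi1 is computed from N, CA, CB and a residue-specific fourth atom (CG for
most residues, OG for serine, OG1 for threonine, CG1 for isoleucine and
valine, SG for cysteine), with the field-standard sign convention (checked
against `bio3d::torsion.xyz`). Torsion angles are invariant under
atom-order reversal; only mirror reflection negates them. Assignment uses
equidistant boundaries between the wells: [0, 120) -> 1, [120, 180] and
[-180, -120) -> 2, [-120, 0) -> 3; for proline the boundary between the
two wells (+27, -25) sits at about +1 degree, and 0 is used as the
documented cut. The well-to-index mapping (1 = gauche+, 2 = trans,
3 = gauche-) follows the listing order of the wells in the state table.

Residues are dropped (emitting UNKNOWN, so the sequence frame is kept)
when the mean B-factor of the four chi1 atoms exceeds 30, when the peptide
C-N bond to the next residue exceeds 1.8 Angstrom (chain break), when the
residue is nonstandard, or when chi1 atoms are missing or at zero
occupancy ("disordered" is not otherwise operationalized; this is our
reading). ALA/GLY have no chi1 atoms and are exempt from the B-factor and
missing-atom checks. The resolution cutoff (< 2.5 Angstrom) applies at the
structure level and is treated as a metadata predicate, since bulk data
harvesting is out of scope. Alternate locations keep the
highest-occupancy conformer.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `identityMin` | 0.75 | fraction | pairs below it risk multiple hits per site; the boundary value is included |
| `bMax` | 30 | B-factor | ambiguous electron density above this |
| `bondMax` | 1.8 | Angstrom | peptide bonds beyond this indicate chain breaks |
| gamma categories `k` | 4 | — | standard +G resolution |
| `alpha` bounds | [0.02, 100] | — | numerically safe range for the shape |
| branch-length bounds | [1e-6, 100] | substitutions/site | optimizer search interval |
| convergence `tol` | 1e-6 | log-likelihood | coordinate-sweep stopping rule |
| KL grid | 200 log-spaced points in [0.01, 5] | time | covers the divergences at which models are applied |
| pseudocount | off (0.5 when enabled) | counts | explicit opt-in imputation for empty submatrices |

Frequencies read from model files may be off from 1 by up to 1e-3 (printed
precision) and are renormalized; larger discrepancies are errors.

## File formats

Rotasequence FASTA comes in two dialects: a single-character dialect
mapping the 55 states, in table row order, onto
`0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghijklmnopqrs` (gap `-`,
unknown `?`), and a human-readable two-token dialect (`F1 W3 A- …`,
whitespace-separated). Model files generalize the PAML `.dat` layout —
lower-triangle exchangeabilities (1485 entries for 55 states) then
frequencies — with `#` headers recording the state order and the scaling
convention, since no serialization standard exists for expanded state
spaces; headerless 20-state files in the classical layout are read
directly. Count matrices are labeled TSV.

## Comparing models across state spaces

A 20-state and a 55-state likelihood are not directly comparable. The
package implements the standard state-space correction: the corrected
log-likelihood of an amino-acid ("compound") model on rotasequence data is
the masked-alignment log-likelihood plus, for every observed tip
character, `log(pi55[d] / pi20[c])` with `d` the expanded state and `c` its
amino acid. AIC on corrected likelihoods ("state-corrected AIC") then
ranks models; for fixed empirical matrices the parameter count is the
number of branch lengths (plus 1 for an estimated gamma shape and
states-1 for +F frequencies, when used) — the exchangeabilities themselves
are not counted, the usual convention for empirical models.

One caveat we verified both analytically and numerically: the per-character
correction assumes tip rotamer states are conditionally independent given
the amino-acid states, which no finite-rate expanded chain satisfies
exactly. For the uniform expansion of a 20-state model (counts spread
evenly over each rotamer submatrix), the fine chain lumps *exactly* onto
the coarse chain — aggregated transition probabilities, masked-data
likelihoods and the Kullback-Leibler information loss are all identical to
machine precision, and the package's tests assert this — but the corrected
coarse likelihood of *fine* data only converges to the fine likelihood as
divergence grows (at t = 0 the two differ by a factor `|R_A|` per
repeated-tip character). The correction is therefore used as the
established model-selection device, not as an identity.

Two reference expansions embed a 20-state model in the 55-state space: the
uniform expansion above (the most-uninformed embedding) and a
frequency-weighted expansion (`nbar_ij = pi55_i pi55_j n_AA'`) that knows
rotamer frequencies but not rotamer replacement preferences. When only
exchangeabilities are available, counts are first reconstructed as
`n_ij = pi_i s_ij pi_j` off the diagonal, with the diagonal chosen so row
sums stay proportional to `pi` — the choice that makes the reconstruction
an exact inverse of the estimation equations up to the rate scale.

Information loss from lumping is quantified per start state (A, R) as the
KL divergence, in bits, between the amino-acid distribution reached at
time t under the expanded model (transition probabilities summed over
target rotamer configurations) and under the 20-state model, and
summarized as the frequency-weighted mean profile over a time grid.

## Exchange-pattern statistics

For each unordered pair of different amino acids with at least two rotamer
configurations (136 three-by-three pairs among the 17 three-well residues,
plus 17 proline pairs, 153 in all), the off-diagonal submatrix of the
normalized counts is tested for independence of the two chi1
configurations (Pearson chi-squared on marginals-based expectations,
Bonferroni-corrected over testable pairs). Association strength uses
Cramer's V with Bergsma's bias correction; the diagonal ratio
(trace/total) measures the tendency to conserve chi1 across the exchange.
The chi-squared machinery accepts the (non-integer) normalized counts as
given, with raw counts equally usable — which scale is more faithful is a
judgment call we leave to the caller. Backbone context similarity is the
integral of the pointwise minimum of two (phi, psi) densities on a 72 x 72
periodic grid (5-degree cells, probability-mass normalization), and its
rank correlation with exchangeabilities is computed globally or per
amino-acid pair (Spearman, average ranks).

## Synthetic data: what it does and does not emulate

The package is fully testable offline through its fixture generators:

- `toyModel()` draws strictly positive symmetric counts with a
  conservation-dominant diagonal (diagonal boosted 10-fold, echoing the
  roughly 6:1 conservation:substitution ratio of real count data) over a
  reduced alphabet (default multiplicities {3, 3, 2, 1}, 9 states, chosen
  so brute-force enumeration oracles stay cheap) or over the full 55-state
  alphabet, and runs the real pipeline end to end.
- `toyStructure()` builds ideal-geometry chains whose chi1 angles equal
  prescribed targets (internal-coordinate placement of the fourth atom),
  with per-residue B-factor and bond-length overrides to exercise each
  filter.
- `plantedFamily()` simulates alignments while recording ancestral
  sequences and per-branch endpoint difference tallies.
- `torsionSamples()` draws (phi, psi) pairs from wrapped-normal mixtures.

Simulated rotasequences have i.i.d. sites, no indels, no alignment error,
no within-rotamer thermal noise, and no correlation between sites or
between sequence and structure quality. Passing tests therefore
demonstrate the correctness of the algorithms under the model's own
assumptions, not robustness to the artefacts of real crystallographic
data.

Simulation conditions follow the study design: random trees with 8-64
taxa and branch lengths uniform on [0.01, 0.5], global branch scalings
spanning 0.001-5, and alignments of 200 or 1,000 sites. Random topologies
use sequential random attachment to a uniformly chosen branch (including
the root stem), which samples labeled rooted binary topologies uniformly;
the simulator draws root states from pi and child states from P(t) per
branch — exact transition-probability sampling, statistically equivalent
to event-level simulation but faster.

## Numerical choices

- Transition probabilities via symmetric eigendecomposition (valid for
  reversible models with positive frequencies), entries clamped to [0, 1];
  P(0) returns the exact identity.
- Pruning rescales partials per node and site; gamma categories are
  combined by log-sum-exp. Reconstruction message passing runs in linear
  space, appropriate for the moderate tree sizes reconstruction targets.
- Branch lengths are optimized coordinate-wise (Brent per branch, at most
  50 sweeps); the gamma shape on a log scale; +F frequencies by BFGS on
  log-ratio coordinates, rebuilding the rate matrix from exchangeabilities
  at every step.
- Neighbor joining ties and the circular tour are made input-order
  invariant by sorting taxa lexicographically before distance computation;
  p-distances use pairwise deletion of gap/unknown sites (the identity
  filter is computed the same way).
- The discretized-gamma mean-method categories deviate from 1 by
  O(1/sqrt(alpha)) even for huge alpha (about 1.3e-3 at alpha = 1e6), so
  "all rates equal 1" holds only in the numerical limit.
- In the KL computation, start-state masses below 1e-14 are treated as
  zero before the 0/0 guard; a genuine positive mass facing a zero
  reference probability reports infinity.

## Scope and limitations

- Exchangeabilities are estimated by counting only; no ML estimation of
  rate matrices from alignments.
- No heuristic tree-topology search: the likelihood machinery optimizes
  branch lengths on a fixed topology, and exhaustive enumeration is only
  feasible for the small trees used by the test oracles. Large-scale
  searches are delegated to external tools via exported model files.
- Only chi1 is modeled; chi2+ angles, indels, codon models and
  nonreversible processes are out of scope. LLO reconstruction keeps the
  original pendant branch length of the removed leaf (the protocol leaves
  it unspecified; results may be mildly sensitive to it).
- Reproducing the published full-scale estimates would require harvesting
  thousands of Pfam families with mapped PDBe structures; the test suite
  and acceptance script instead verify the machinery on synthetic models
  at desk scale (16-taxon, 1,000-site identifiability replicates;
  8-taxon, 200-site reconstruction designs; 10,000-site parameter
  recovery), sizes chosen to give stable statistics from a complete run
  in minutes.
- The command-line front end (`inst/scripts/rotasub.R`) is a thin wrapper
  over the exported functions; the R API is the primary interface.
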