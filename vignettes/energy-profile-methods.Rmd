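---
title: "Energy profiles: model, parameters and design choices"
author: "eprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy profiles: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
coarse-grained model, every tunable that matters, the numerical conventions,
what the synthetic generators do and do not emulate, and the design choices
made where the method description leaves room.

## 1. The model

### Inside/outside classification

The elementary observable is a binary buriedness call per residue, computed
from Cα/Cβ geometry only. For residue $i$, let $c$ be the unweighted
centroid of all Cα atoms within radius $r$ (default 5 Å) of
$C_{\alpha,i}$ — the residue itself is excluded, since including it drags
$c$ toward $C_{\alpha,i}$ and trivializes the test (a literal-inclusion
flag `includeSelf` restores it). The residue is *inside* iff

$$\lVert C_{\alpha,i} - c\rVert < r
  \quad\lor\quad
  \sigma\,(C_{\alpha,i}-C_{\beta,i})\cdot(C_{\alpha,i}-c) < 0,$$

with orientation sign $\sigma = +1$ by default. Two properties of this rule
deserve attention:

* **Geometric degeneracy.** Because $c$ is a convex combination of points
  inside the $r$-ball, $\lVert C_{\alpha,i}-c\rVert < r$ holds *whenever the
  residue has any neighbor within $r$* — except in the boundary case of a
  single neighbor at exactly $r$, where the centroid sits exactly on the
  sphere and the strict `<` fails. In compactly packed structures the
  distance disjunct therefore fires almost everywhere and the side-chain
  term is rarely consulted. We implement the rule literally rather than
  guess an intended variant, and expose `radius` and `orientationSign` so
  users can explore alternatives.
* **Orientation convention.** Read literally, the dot-product disjunct
  classifies a residue as inside when its side chain points *away* from the
  local center, which is the opposite of the usual packing intuition
  (buried side chains point into the core). `orientationSign = -1` flips to
  the side-chain-toward-center convention; the bundled synthetic statistics
  are computed under this flipped convention because it is the one in which
  controlled buriedness can be generated and recovered (Section 4).

A residue with no neighbor within $r$ is classified outside (surface-like);
a residue without a real or reconstructed Cβ falls back to the distance
disjunct alone. Glycines and incomplete side chains get an ideal Cβ
reconstructed from the backbone (`virtualCbeta()`: bond length 1.53 Å,
N–Cα–Cβ angle 110.5°, L-chirality; validated to land within 0.3 Å of a
deposited alanine Cβ).

### Pseudoenergies and profile

Buriedness counts over a structure set give, per amino-acid type $i$,

$$e^*_i = -\ln\frac{n_{\mathrm{in},i} + q}{n_{\mathrm{out},i} + q},$$

with pseudocount $q = 1$ by default so $e^*$ stays finite for types that
are never (or always) buried. $k_BT$ is constant in the model and omitted:
energies are in arbitrary units, proportional to physical energies. The
sign convention follows Boltzmann inversion: a type observed buried more
often than exposed has $e^* < 0$.

The environment of residue $i$ is
$\mathrm{Env}(i) = \{j \ne i : \lVert C_{\alpha,i}-C_{\alpha,j}\rVert \le
8\,\text{Å}\}$, the boundary **inclusive** at exactly 8 Å and with *no*
sequence-separation exclusion (sequence neighbors count). The total residue
energy is

$$E^*_i = \sum_{j \in \mathrm{Env}(i)} \left(e^*_i + e^*_j\right)
        = |\mathrm{Env}(i)|\,e^*_i + \sum_{j \in \mathrm{Env}(i)} e^*_j,$$

and the profile is the ordered vector of all $E^*_i$. Contacts are found on
a full vectorized distance matrix (fast in R up to a few thousand residues);
the test suite checks it against a naive double loop, the pair-sum identity
$\sum_i E^*_i = \sum_{\{i,j\}\,\text{in contact}} 2(e^*_i+e^*_j)$, and the
environment decomposition above. Profiles are computed per chain by
default (`splitChains()`); merging chains is available and changes energies
at interfaces because contacts then cross chains.

## 2. Alignment and dScore

Energies are discretized by an `EnergyBinner`: a normal distribution is
fitted (mean, sd) to a reference sample and the bin boundaries are its
$k/n_\mathrm{bins}$ quantiles, giving bins of equal probability mass. The
pair score of two energies is $s_\mathrm{max} - |b_a - b_b|$ with $b$ the
bin indices, so the best possible pair score is $\delta = s_\mathrm{max}$,
attained exactly when both energies share a bin. This "similarity =
maximum minus bin distance" orientation is the only reading under which
$x_\mathrm{opt} = \delta(|A|+|B|)/2$ bounds every alignment score from
above, which the dScore formula requires.

Profiles are aligned by Needleman–Wunsch (global, default) or
Smith–Waterman (local, zero floor, empty alignment allowed) with a linear
gap penalty. Significance:

$$\mathrm{dScore}(x_r) = -\log_{10}
  \frac{x_r - \bar{x}_p}{x_\mathrm{opt} - \bar{x}_p},$$

where $\bar{x}_p$ is the mean optimal score over `nPerm` rounds in which
the entry order of *both* profiles is independently shuffled and the pair
realigned. The unit is the ban (base-10 log). Identity gives 0 bans exactly
— reported as exact 0 whenever $x_r = x_\mathrm{opt}$, independent of the
permutation outcome — and alignments under 2.5 bans are flagged
significant.

Defaults and their rationale (all configurable):

| parameter | default | units | rationale |
|---|---|---|---|
| `radius` (buriedness) | 5 | Å | neighbor sphere of the inside/outside rule |
| `cutoff` (contacts) | 8 | Å | contact function boundary, inclusive |
| `pseudocount` | 1 | counts | keeps $e^*$ finite for rare types |
| `nBins` | 20 | — | one bin per amino-acid type scale; method description leaves the count open |
| `sMax` ($\delta$) | `nBins` | score | best pair score; makes bin distance and similarity share one scale |
| `gap` | `sMax/2` | score | linear; unspecified by the method, half the maximal match keeps gaps competitive with poor matches |
| `nPerm` | 100 | — | permutation rounds; standard error of $\bar{x}_p$ well under a bin |
| significance | 2.5 | bans | stated threshold |
| `cap` | 10 | bans | ceiling for $x_r \le \bar{x}_p$ (log of a non-positive ratio) and for vanishing ratios |

Numerical conventions: deterministic DP tie-breaking (diagonal, then gap in
B, then gap in A; the local-alignment start cell is the maximal cell with
smallest row then column index); energies beyond the fitted range clamp to
the edge bins; a zero-variance reference sample is a hard error (no binner
exists); $\bar{x}_p \ge x_\mathrm{opt}$ is a degenerate-null error.
Symmetry in the argument order is guaranteed by canonicalizing the profile
pair internally (by length, then energies) before drawing permutations, so
`alignProfiles(A, B)` and `alignProfiles(B, A)` return identical scores
under the same seed. The binner reference sample is the pooled energies of
the two profiles; a fixed background binner can be supplied instead.

Against the permutation null, note what a *shuffled copy* of a profile is:
its raw score is itself a draw from that null, so its dScore is large but
stochastic (about 10 bans in the median, occasionally small). Tests
therefore assert medians over replicates, never single draws.

## 3. MEPAL

The multiple alignment is progressive: (1) all-vs-all pairwise dScores;
(2) UPGMA agglomeration, recording merge order — the distance between
merged clusters is the size-weighted mean, equivalently the mean over all
cross pairs of the original matrix; ties are broken by lexicographic
cluster label (a cluster is labelled by its smallest member), making the
tree deterministic; (3) profiles/groups merged along the recorded order
with the same DP machinery, a group column scored against another column by
the *arithmetic mean* of pair scores over non-gap members (chosen for
consistency with UPGMA's unweighted averaging; the method description says
only "same techniques as pairwise"); gaps from earlier merges are never
reopened. The binner is fitted once on the pooled energies of all profiles
rather than refitted per merge, so column scores are comparable across the
whole procedure.

Per column, the **consensus** is the member energy with maximal summed pair
score to the other members (ties toward the lower energy, i.e. the more
stable state), and **conservation** is the summed pairwise score divided by
(number of pairs) × $\delta$, so identical members give exactly 1.0.
Columns with a single non-gap member report conservation 1.0 by convention
(`singleValue = NA` marks them as not assessable instead). Guide trees
export to Newick via `ape` with ultrametric leaf depths (merge
distance / 2).

## 4. Synthetic generators and the bundled statistics

The generators make every stage testable without external structure sets:

* `makeHelix()` — ideal α-helical Cα trace (radius 2.3 Å, rise 1.5 Å,
  100°/residue; consecutive Cα ≈ 3.8 Å) with Cβ pointing radially outward;
  optional Gaussian coordinate jitter. Emulates the geometry of the helical
  membrane segments the potential targets.
* `makeGlobule()` — compact lattice blob (3.8 Å spacing) with Cβ
  orientation assignable per residue; used for contact-rich fixtures.
* `makeBuriedPairs()` — the parameter-recovery design. Because of the
  degeneracy of Section 1, a *compact* structure cannot express a
  controlled buriedness probability: any residue with a neighbor inside the
  radius is "inside" regardless of its side chain. The one regime in which
  the orientation term decides is a single neighbor at exactly the
  classification radius, where the centroid sits exactly on the sphere and
  the strict `<` fails. The generator therefore places isolated residue
  pairs separated by exactly `radius` (pairs far apart from each other) and
  points each Cβ at its partner with probability $p$; under
  `orientationSign = -1` such residues are classified inside. The recovered
  $e^*$ then converges to $-\ln(p/(1-p))$, which the tests verify at
  $p \in \{0.2, 0.5, 0.8\}$ with 10,000 classified residues (±0.1).

All generators are pure functions of their arguments and seed, and restore
the caller's RNG state.

The bundled table (`defaultEnergyTable()`, `inst/extdata/synthetic_stats.tsv`)
is computed by `syntheticEnergyTable()`: 500 pairs per amino acid, buried
probability $p_a = 1/(1+e^{-\mathrm{KD}_a/2})$ from Kyte–Doolittle
hydropathy, so $e^*_a \approx -\mathrm{KD}_a/2 \in [-2.25, 2.25]$ —
hydrophobic types come out stabilizing (negative), polar ones destabilizing,
with a realistic spread for the binner. It is **synthetic**: it makes demos
and tests self-contained, and a test pins the TSV to its seeded
regeneration. It is not derived from experimental structures; biological
use requires user-computed statistics from an appropriate, non-redundant
structure set of the same structural class as the queries — mixing
statistics across classes (e.g. applying globular statistics to membrane
proteins) invalidates the energies.

What passing tests on these fixtures shows: the formulas, the DP optimality,
the calibration and the multiple-alignment machinery are implemented
correctly. What they do not show: that the potential discriminates real
folds — helices here have random sequences, globules are lattices, neither
has loops, sheets, side-chain packing or a membrane, and the bundled
statistics encode a hydropathy prior rather than measured buriedness.

## 5. Evaluation utilities

`fragmentProfiles()` slides a 5-residue window (step 1); each fragment
carries the label of its center residue, and labels are held out from
clustering. `neuralGas()` is the standard prototype-adaptation algorithm
(rank-based update, exponentially decaying learning rate 0.5→0.005 and
neighborhood range $k/2$→0.01, defaults 100 steps per prototype — the
source method leaves these open, so they are documented configuration, not
inferred values). `nmi()` normalizes mutual information by the arithmetic
mean of the entropies by default (min/max/geometric offered), matching the
common NMI variant; `repeatClustering()` resamples 600 fragments per
repeat, 100 repeats, and reports mean ± sd. `spearmanRho()` delegates to
`stats::cor(method = "spearman")` with explicit errors for constant input.
The headline correlations and NMI values reported for real membrane-protein
sets depend on external structure databases and are out of scope here; the
procedures are implemented and verified on synthetic data with known
ground truth.

## 6. Problem sizes and limitations

The test suite and the acceptance script run at deliberately modest sizes —
60–80-residue helices, globules up to 30 residues for oracle comparisons,
10,000 classified residues per recovery setting, 200 short profile pairs
against exhaustive alignment enumeration, 500 random matrices against
brute-force UPGMA — chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo standard errors far inside the asserted
tolerances.

Known limitations:

* the inside/outside rule's distance disjunct saturates in compact
  structures (Section 1); the package documents rather than repairs this;
* PDB input only (no mmCIF, assemblies, occupancy weighting or hydrogens);
  first altloc kept; MSE mapped to MET, other non-canonical residues
  dropped;
* linear gap penalties only are trained/used by default (affine gaps are
  not implemented); no analytic E-values beyond the permutation scheme;
* progressive alignment has no iterative refinement, and projection
  consistency under profile removal is not guaranteed (only per-profile
  entry order is);
* the side-chain environment is Cα/Cβ-only; no solvent-accessible surface
  computation.
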