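# S4 classes for structures, buriedness statistics, profiles, alignments.

#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Minimal per-residue protein structure
#'
#' Holds the coarse representation the energy model needs: one row per
#' residue with chain id, author residue number, insertion code, one-letter
#' amino-acid code, the C-alpha coordinate and (possibly missing) C-beta
#' coordinate, all in Angstrom. Residue order follows file order within each
#' chain.
#'
#' @slot id character(1) structure identifier.
#' @slot residues data.frame with columns `chain`, `resno`, `ins`, `aa`,
#'   `ca_x`, `ca_y`, `ca_z`, `cb_x`, `cb_y`, `cb_z` (`cb_*` may be `NA`),
#'   and logical `cb_virtual` marking reconstructed C-beta positions.
#'
#' @export
setClass("EPStructure",
  representation(id = "character", residues = "data.frame"),
  validity = function(object) {
    need <- c("chain", "resno", "ins", "aa",
              "ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z", "cb_virtual")
    if (!all(need %in% names(object@residues)))
      return(paste("residues must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@residues) < 1L)
      return("a structure must contain at least one residue")
    if (!all(object@residues$aa %in% aminoAcids()))
      return("all residues must carry a canonical one-letter amino-acid code")
    if (anyNA(object@residues[, c("ca_x", "ca_y", "ca_z")]))
      return("every residue must have a C-alpha coordinate")
    TRUE
  }
)

#' Per-amino-acid buriedness counts
#'
#' Absolute frequencies of each canonical amino acid being classified as
#' buried (inside) or exposed (outside) over a structure set.
#'
#' @slot counts data.frame with columns `aa`, `n_in`, `n_out` (20 rows).
#' @slot sourceSet character(1) label of the structure set used.
#' @slot radius numeric(1) neighbor-sphere radius in Angstrom.
#' @slot orientationSign numeric(1) sign convention used for the
#'   side-chain orientation term (+1 literal, -1 flipped).
#'
#' @export
setClass("BuriednessCounts",
  representation(counts = "data.frame", sourceSet = "character",
                 radius = "numeric", orientationSign = "numeric"),
  validity = function(object) {
    df <- object@counts
    if (!all(c("aa", "n_in", "n_out") %in% names(df)))
      return("counts needs columns aa, n_in, n_out")
    if (!identical(sort(df$aa), aminoAcids()))
      return("counts must contain exactly the 20 canonical amino acids")
    if (any(df$n_in < 0) || any(df$n_out < 0))
      return("counts must be non-negative")
    TRUE
  }
)

#' Per-amino-acid pseudoenergy table
#'
#' Inverse-Boltzmann pseudoenergies e* = -ln((n_in + q)/(n_out + q)) in
#' arbitrary units (a.u.), together with the counts they were derived from
#' and provenance metadata.
#'
#' @slot table data.frame with columns `aa`, `n_in`, `n_out`, `e_star`.
#' @slot provenance named list: `source_set`, `radius`, `pseudocount`,
#'   `orientation_sign`, `created`.
#'
#' @export
setClass("PseudoEnergyTable",
  representation(table = "data.frame", provenance = "list"),
  validity = function(object) {
    df <- object@table
    if (!all(c("aa", "n_in", "n_out", "e_star") %in% names(df)))
      return("table needs columns aa, n_in, n_out, e_star")
    if (!identical(sort(df$aa), aminoAcids()))
      return("table must contain exactly the 20 canonical amino acids")
    if (any(!is.finite(df$e_star)))
      return("pseudoenergies must be finite (use a positive pseudocount)")
    TRUE
  }
)

#' Per-residue energy profile
#'
#' The one-dimensional transformation of a structure: one total pseudoenergy
#' E*_i per residue, in structure order.
#'
#' @slot id character(1) profile identifier.
#' @slot entries data.frame with columns `chain`, `resno`, `aa`, `energy`.
#' @slot statsProvenance character(1) label of the pseudoenergy table used.
#' @slot contactRadius numeric(1) contact cutoff in Angstrom.
#'
#' @export
setClass("EnergyProfile",
  representation(id = "character", entries = "data.frame",
                 statsProvenance = "character", contactRadius = "numeric"),
  validity = function(object) {
    df <- object@entries
    if (!all(c("chain", "resno", "aa", "energy") %in% names(df)))
      return("entries needs columns chain, resno, aa, energy")
    if (nrow(df) < 1L) return("a profile must contain at least one entry")
    if (any(!is.finite(df$energy))) return("profile energies must be finite")
    TRUE
  }
)

#' Quantile binner for energies
#'
#' Discretizes energies into `nBins` intervals of equal probability mass
#' under a normal distribution fitted (mean, sd) to a reference sample.
#'
#' @slot nBins integer(1) number of bins (>= 2).
#' @slot mean,sd numeric(1) fitted normal parameters.
#' @slot boundaries numeric vector of the nBins-1 interior quantiles,
#'   strictly increasing.
#'
#' @export
setClass("EnergyBinner",
  representation(nBins = "integer", mean = "numeric", sd = "numeric",
                 boundaries = "numeric"),
  validity = function(object) {
    if (object@nBins < 2L) return("nBins must be >= 2")
    if (length(object@boundaries) != object@nBins - 1L)
      return("boundaries must have length nBins - 1")
    if (any(diff(object@boundaries) <= 0))
      return("boundaries must be strictly increasing")
    TRUE
  }
)

#' Pairwise profile alignment result
#'
#' @slot idA,idB character(1) profile identifiers.
#' @slot pairs integer matrix with columns `a`, `b`; `NA` marks a gap.
#' @slot xR numeric(1) raw alignment score.
#' @slot xOpt numeric(1) best possible score, delta * (|A| + |B|) / 2.
#' @slot xPerm numeric(1) mean score over permuted realignments (NA if not
#'   computed).
#' @slot dScore numeric(1) distance score in bans (NA if not computed).
#' @slot nPerm integer(1) number of permutations.
#' @slot seed integer(1) RNG seed used for permutations.
#' @slot mode character(1) "global" or "local".
#' @slot significant logical(1) whether dScore < 2.5 bans.
#'
#' @export
setClass("AlignmentResult",
  representation(idA = "character", idB = "character", pairs = "matrix",
                 xR = "numeric", xOpt = "numeric", xPerm = "numeric",
                 dScore = "numeric", nPerm = "integer", seed = "integer",
                 mode = "character", significant = "logical"),
  validity = function(object) {
    p <- object@pairs
    if (ncol(p) != 2L) return("pairs must have two columns")
    for (k in 1:2) {
      v <- p[, k]
      v <- v[!is.na(v)]
      if (length(v) > 1L && any(diff(v) <= 0))
        return("aligned index sequences must be strictly increasing")
    }
    TRUE
  }
)

#' UPGMA guide tree
#'
#' Rooted binary tree over profile ids, with recorded merge order and
#' ultrametric node heights (half the cluster distance at each merge).
#'
#' @slot labels character vector of leaf labels.
#' @slot merge integer matrix in `stats::hclust` convention: negative
#'   entries index leaves, positive entries earlier merges.
#' @slot height numeric vector of merge distances (cluster-average
#'   distances, i.e. twice the ultrametric node height).
#'
#' @export
setClass("GuideTree",
  representation(labels = "character", merge = "matrix", height = "numeric"),
  validity = function(object) {
    n <- length(object@labels)
    if (n < 2L) return("a guide tree needs at least two leaves")
    if (nrow(object@merge) != n - 1L) return("merge must have n-1 rows")
    if (length(object@height) != n - 1L) return("height must have n-1 entries")
    if (any(diff(object@height) < -1e-9))
      return("merge heights must be non-decreasing (ultrametric)")
    TRUE
  }
)

#' Multiple energy profile alignment
#'
#' Aligned columns over two or more profiles plus per-column consensus
#' energy and conservation.
#'
#' @slot ids character vector of profile identifiers (row order).
#' @slot energy numeric matrix, profiles x columns; `NA` marks gaps.
#' @slot aa character matrix of one-letter codes, same shape as `energy`.
#' @slot consensus numeric vector of per-column consensus energies.
#' @slot conservation numeric vector in `[0, 1]`, one per column.
#' @slot binner the [EnergyBinner-class] used for column scoring.
#' @slot sMax numeric(1) maximal pairwise energy score delta.
#'
#' @export
setClass("ProfileMSA",
  representation(ids = "character", energy = "matrix", aa = "matrix",
                 consensus = "numeric", conservation = "numeric",
                 binner = "EnergyBinner", sMax = "numeric"),
  validity = function(object) {
    if (nrow(object@energy) != length(object@ids))
      return("energy must have one row per profile id")
    if (!identical(dim(object@energy), dim(object@aa)))
      return("energy and aa must have identical dimensions")
    nc <- ncol(object@energy)
    if (length(object@consensus) != nc || length(object@conservation) != nc)
      return("consensus and conservation must have one value per column")
    if (any(object@conservation < -1e-12 | object@conservation > 1 + 1e-12))
      return("conservation must lie in [0, 1]")
    if (any(colSums(!is.na(object@energy)) == 0))
      return("alignment columns must contain at least one non-gap entry")
    TRUE
  }
)
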