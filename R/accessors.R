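# Accessors and show() methods.

#' @describeIn EPStructure-class structure identifier
#' @param object an object of the documented class
#' @export
setGeneric("structureId", function(object) standardGeneric("structureId"))
#' @export
setMethod("structureId", "EPStructure", function(object) object@id)

#' @describeIn EPStructure-class residue table (one row per residue)
#' @export
setGeneric("residueTable", function(object) standardGeneric("residueTable"))
#' @export
setMethod("residueTable", "EPStructure", function(object) object@residues)

#' @describeIn EPStructure-class number of residues
#' @param x an `EPStructure`
#' @export
setMethod("length", "EPStructure", function(x) nrow(x@residues))

#' C-alpha coordinates of a structure
#'
#' @param object an [EPStructure-class]
#' @return numeric matrix, residues x 3 (Angstrom).
#' @export
setGeneric("caCoords", function(object) standardGeneric("caCoords"))
#' @export
setMethod("caCoords", "EPStructure", function(object) {
  m <- as.matrix(object@residues[, c("ca_x", "ca_y", "ca_z")])
  dimnames(m) <- NULL
  m
})

#' C-beta coordinates of a structure
#'
#' Rows are `NA` where no real or reconstructed C-beta is available.
#'
#' @param object an [EPStructure-class]
#' @return numeric matrix, residues x 3 (Angstrom), possibly with NA rows.
#' @export
setGeneric("cbCoords", function(object) standardGeneric("cbCoords"))
#' @export
setMethod("cbCoords", "EPStructure", function(object) {
  m <- as.matrix(object@residues[, c("cb_x", "cb_y", "cb_z")])
  dimnames(m) <- NULL
  m
})

setMethod("show", "EPStructure", function(object) {
  df <- object@residues
  cat(sprintf("EPStructure '%s': %d residues, %d chain(s)\n",
              object@id, nrow(df), length(unique(df$chain))))
  cat(sprintf("  chains: %s\n", paste(unique(df$chain), collapse = ", ")))
  cat(sprintf("  C-beta: %d real, %d virtual, %d absent\n",
              sum(!is.na(df$cb_x) & !df$cb_virtual),
              sum(df$cb_virtual, na.rm = TRUE),
              sum(is.na(df$cb_x))))
})

#' @describeIn BuriednessCounts-class counts table (aa, n_in, n_out)
#' @param object an object of the documented class
#' @export
setGeneric("countsTable", function(object) standardGeneric("countsTable"))
#' @export
setMethod("countsTable", "BuriednessCounts", function(object) object@counts)

setMethod("show", "BuriednessCounts", function(object) {
  cat(sprintf("BuriednessCounts from '%s' (radius %.2f A, sign %+d)\n",
              object@sourceSet, object@radius, object@orientationSign))
  cat(sprintf("  %d residues classified: %d inside, %d outside\n",
              sum(object@counts$n_in) + sum(object@counts$n_out),
              sum(object@counts$n_in), sum(object@counts$n_out)))
})

#' @describeIn PseudoEnergyTable-class full table (aa, n_in, n_out, e_star)
#' @param object an object of the documented class
#' @export
setGeneric("energyTable", function(object) standardGeneric("energyTable"))
#' @export
setMethod("energyTable", "PseudoEnergyTable", function(object) object@table)

#' Pseudoenergy lookup
#'
#' @param object a [PseudoEnergyTable-class]
#' @param aa character vector of one-letter amino-acid codes
#' @return numeric vector of pseudoenergies e* in a.u.
#' @export
setGeneric("energyFor", function(object, aa) standardGeneric("energyFor"))
#' @export
setMethod("energyFor", "PseudoEnergyTable", function(object, aa) {
  idx <- match(aa, object@table$aa)
  if (anyNA(idx))
    stop("amino acid(s) absent from pseudoenergy table: ",
         paste(unique(aa[is.na(idx)]), collapse = ", "))
  object@table$e_star[idx]
})

setMethod("show", "PseudoEnergyTable", function(object) {
  pv <- object@provenance
  cat(sprintf("PseudoEnergyTable from '%s' (radius %.2f A, pseudocount %g)\n",
              pv$source_set, pv$radius, pv$pseudocount))
  rng <- range(object@table$e_star)
  cat(sprintf("  e* range: [%.3f, %.3f] a.u.\n", rng[1], rng[2]))
})

#' @describeIn EnergyProfile-class profile identifier
#' @export
setMethod("structureId", "EnergyProfile", function(object) object@id)

#' @describeIn EnergyProfile-class entry table (chain, resno, aa, energy)
#' @export
setGeneric("profileEntries", function(object) standardGeneric("profileEntries"))
#' @export
setMethod("profileEntries", "EnergyProfile", function(object) object@entries)

#' Per-residue energies of a profile
#'
#' @param object an [EnergyProfile-class]
#' @return numeric vector of total residue energies E*_i in a.u.
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))
#' @export
setMethod("energies", "EnergyProfile", function(object) object@entries$energy)

#' @describeIn EnergyProfile-class number of residues in the profile
#' @param x an `EnergyProfile`
#' @export
setMethod("length", "EnergyProfile", function(x) nrow(x@entries))

setMethod("show", "EnergyProfile", function(object) {
  e <- object@entries$energy
  cat(sprintf("EnergyProfile '%s': %d residues (cutoff %.1f A, stats: %s)\n",
              object@id, length(e), object@contactRadius,
              object@statsProvenance))
  cat(sprintf("  E* range: [%.3f, %.3f] a.u., mean %.3f\n",
              min(e), max(e), mean(e)))
})

setMethod("show", "EnergyBinner", function(object) {
  cat(sprintf("EnergyBinner: %d equal-mass bins of N(%.4f, %.4f)\n",
              object@nBins, object@mean, object@sd))
})

#' @describeIn AlignmentResult-class dScore in bans
#' @param object an object of the documented class
#' @export
setGeneric("dScore", function(object) standardGeneric("dScore"))
#' @export
setMethod("dScore", "AlignmentResult", function(object) object@dScore)

#' @describeIn AlignmentResult-class aligned index pairs (NA = gap)
#' @export
setGeneric("alignedPairs", function(object) standardGeneric("alignedPairs"))
#' @export
setMethod("alignedPairs", "AlignmentResult", function(object) object@pairs)

#' @describeIn AlignmentResult-class raw, optimal and permutation-mean scores
#' @export
setGeneric("alignmentScores", function(object) standardGeneric("alignmentScores"))
#' @export
setMethod("alignmentScores", "AlignmentResult", function(object) {
  c(x_r = object@xR, x_opt = object@xOpt, x_perm = object@xPerm)
})

#' @describeIn AlignmentResult-class TRUE if dScore < 2.5 bans
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))
#' @export
setMethod("isSignificant", "AlignmentResult", function(object) object@significant)

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult (%s): '%s' vs '%s'\n",
              object@mode, object@idA, object@idB))
  cat(sprintf("  x_r = %.3f, x_opt = %.3f, x_perm = %.3f\n",
              object@xR, object@xOpt, object@xPerm))
  if (is.finite(object@dScore))
    cat(sprintf("  dScore = %.4f bans (%ssignificant at 2.5 bans)\n",
                object@dScore, if (isTRUE(object@significant)) "" else "not "))
})

setMethod("show", "GuideTree", function(object) {
  cat(sprintf("GuideTree (UPGMA): %d leaves, root height %.4f\n",
              length(object@labels), max(object@height) / 2))
  cat(sprintf("  leaves: %s\n", paste(object@labels, collapse = ", ")))
})

#' @describeIn ProfileMSA-class per-column consensus energies
#' @param object an object of the documented class
#' @export
setGeneric("consensusEnergies", function(object) standardGeneric("consensusEnergies"))
#' @export
setMethod("consensusEnergies", "ProfileMSA", function(object) object@consensus)

#' @describeIn ProfileMSA-class per-column conservation in [0, 1]
#' @export
setGeneric("conservation", function(object) standardGeneric("conservation"))
#' @export
setMethod("conservation", "ProfileMSA", function(object) object@conservation)

#' @describeIn ProfileMSA-class energy matrix (profiles x columns, NA = gap)
#' @export
setGeneric("alignmentEnergies", function(object) standardGeneric("alignmentEnergies"))
#' @export
setMethod("alignmentEnergies", "ProfileMSA", function(object) {
  m <- object@energy
  rownames(m) <- object@ids
  m
})

#' @describeIn ProfileMSA-class number of alignment columns
#' @param x a `ProfileMSA`
#' @export
setMethod("length", "ProfileMSA", function(x) ncol(x@energy))

setMethod("show", "ProfileMSA", function(object) {
  cat(sprintf("ProfileMSA: %d profiles, %d columns\n",
              length(object@ids), ncol(object@energy)))
  cat(sprintf("  mean conservation %.3f (min %.3f)\n",
              mean(object@conservation), min(object@conservation)))
})
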