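# Inside/outside classification of residues and inverse-Boltzmann
# pseudoenergies.
#
# A residue i is classified "inside" when
#   ||Ca_i - c|| < r   OR   sign * (Ca_i - Cb_i) . (Ca_i - c) < 0,
# where c is the centroid of all C-alpha atoms within r Angstrom of Ca_i
# (default r = 5). Note the geometric degeneracy of the literal rule: the
# centroid of any non-empty neighbor set lies strictly inside the r-ball,
# so the distance disjunct fires whenever a residue has at least one
# neighbor, except in the boundary case of a single neighbor at exactly r.
# The rule is implemented literally; `radius` and `orientationSign` are
# exposed so users can work in the flipped, side-chain-toward-center
# convention (orientationSign = -1).

#' Local C-alpha centroid around a residue
#'
#' Unweighted mean of the C-alpha coordinates of all residues within
#' `radius` of residue `i`'s C-alpha. Residue `i` itself is excluded by
#' default (including it drags the centroid toward Ca_i and trivializes the
#' distance criterion).
#'
#' @param structure an [EPStructure-class]
#' @param i residue index (1-based)
#' @param radius neighbor-sphere radius in Angstrom (default 5)
#' @param includeSelf include residue i itself in the centroid
#' @return numeric(3) centroid, or `NULL` if no residue lies within radius
#' @export
localCenter <- function(structure, i, radius = 5, includeSelf = FALSE) {
  ca <- caCoords(structure)
  stopifnot(i >= 1L, i <= nrow(ca), radius > 0)
  d <- sqrt(colSums((t(ca) - ca[i, ])^2))
  sel <- d <= radius
  if (!includeSelf) sel[i] <- FALSE
  if (!any(sel)) return(NULL)
  colMeans(ca[sel, , drop = FALSE])
}

#' Classify a residue as inside (buried) or outside (exposed)
#'
#' Applies the inside/outside rule: inside iff the local C-alpha centroid
#' `c` lies closer than `radius` to Ca_i, or the side-chain orientation term
#' `orientationSign * (Ca_i - Cb_i) . (Ca_i - c)` is negative. A residue
#' with no neighbor within `radius` is outside (surface-like); a residue
#' without any C-beta is classified by the distance criterion alone.
#'
#' @inheritParams localCenter
#' @param orientationSign +1 applies the rule literally (side chain pointing
#'   away from the local center counts as inside); -1 flips to the
#'   side-chain-toward-center convention
#' @return logical(1): TRUE = inside
#' @export
classifyInside <- function(structure, i, radius = 5, orientationSign = 1,
                           includeSelf = FALSE) {
  stopifnot(orientationSign %in% c(-1, 1))
  cc <- localCenter(structure, i, radius = radius, includeSelf = includeSelf)
  if (is.null(cc)) return(FALSE)
  ca <- caCoords(structure)[i, ]
  if (.vnorm(ca - cc) < radius) return(TRUE)
  cb <- cbCoords(structure)[i, ]
  if (anyNA(cb)) return(FALSE)
  orientationSign * sum((ca - cb) * (ca - cc)) < 0
}

# vectorized inside/outside over all residues of one structure; one full
# distance matrix instead of n localCenter() calls
.classifyAll <- function(structure, radius, orientationSign, includeSelf) {
  ca <- caCoords(structure)
  cb <- cbCoords(structure)
  n <- nrow(ca)
  D <- as.matrix(stats::dist(ca))
  sel <- D <= radius
  if (!includeSelf) diag(sel) <- FALSE
  out <- logical(n)
  for (i in seq_len(n)) {
    nb <- sel[i, ]
    if (!any(nb)) next
    cc <- colMeans(ca[nb, , drop = FALSE])
    if (.vnorm(ca[i, ] - cc) < radius) { out[i] <- TRUE; next }
    if (anyNA(cb[i, ])) next
    out[i] <- orientationSign * sum((ca[i, ] - cb[i, ]) * (ca[i, ] - cc)) < 0
  }
  out
}

#' Accumulate buriedness counts over a structure set
#'
#' Classifies every residue of every structure and tallies, per canonical
#' amino acid, how often it was inside (n_in) and outside (n_out).
#'
#' @param structures list of [EPStructure-class] (a single structure is
#'   also accepted)
#' @param radius neighbor-sphere radius in Angstrom (default 5)
#' @param orientationSign see [classifyInside()]
#' @param sourceSet text label recording the origin of the set
#' @param includeSelf see [localCenter()]
#' @return a [BuriednessCounts-class]
#' @export
accumulateCounts <- function(structures, radius = 5, orientationSign = 1,
                             sourceSet = "unnamed set", includeSelf = FALSE) {
  if (methods::is(structures, "EPStructure")) structures <- list(structures)
  if (length(structures) == 0L) stop("need at least one structure")
  aas <- aminoAcids()
  nin <- stats::setNames(integer(20), aas)
  nout <- stats::setNames(integer(20), aas)
  for (s in structures) {
    df <- residueTable(s)
    inside <- .classifyAll(s, radius = radius,
                           orientationSign = orientationSign,
                           includeSelf = includeSelf)
    tin <- table(df$aa[inside])
    tout <- table(df$aa[!inside])
    nin[names(tin)] <- nin[names(tin)] + as.integer(tin)
    nout[names(tout)] <- nout[names(tout)] + as.integer(tout)
  }
  methods::new("BuriednessCounts",
               counts = data.frame(aa = aas, n_in = unname(nin),
                                   n_out = unname(nout),
                                   stringsAsFactors = FALSE),
               sourceSet = sourceSet, radius = radius,
               orientationSign = orientationSign)
}

#' Convert buriedness counts to pseudoenergies
#'
#' Inverse Boltzmann: e*_i = -ln((n_in,i + q)/(n_out,i + q)) with
#' pseudocount q. The Boltzmann factor k_B*T is a constant of the model and
#' omitted, so energies are reported in arbitrary units (a.u.). An amino
#' acid observed buried more often than exposed gets e* < 0.
#'
#' @param counts a [BuriednessCounts-class]
#' @param pseudocount non-negative smoothing count q (default 1; q = 0
#'   reproduces the raw ratio but fails on empty categories)
#' @return a [PseudoEnergyTable-class]
#' @export
pseudoEnergies <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  df <- countsTable(counts)
  if (pseudocount == 0 && any(df$n_in + df$n_out == 0))
    stop("undefined ratio: amino acid with no observations and pseudocount 0")
  e <- -log((df$n_in + pseudocount) / (df$n_out + pseudocount))
  if (any(!is.finite(e)))
    stop("non-finite pseudoenergy; use a positive pseudocount")
  methods::new("PseudoEnergyTable",
               table = data.frame(aa = df$aa, n_in = df$n_in,
                                  n_out = df$n_out, e_star = e,
                                  stringsAsFactors = FALSE),
               provenance = list(source_set = counts@sourceSet,
                                 radius = counts@radius,
                                 pseudocount = pseudocount,
                                 orientation_sign = counts@orientationSign,
                                 created = "eprofiler"))
}

#' Write a pseudoenergy table to TSV
#'
#' Header metadata lines are `#`-prefixed (`source_set`, `radius`,
#' `pseudocount`, `orientation_sign`, `version`), followed by a column
#' header and 20 data rows `aa n_in n_out e_star`.
#'
#' @param table a [PseudoEnergyTable-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeStats <- function(table, file) {
  pv <- table@provenance
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# source_set\t%s", pv$source_set),
    sprintf("# radius\t%s", format(pv$radius)),
    sprintf("# pseudocount\t%s", format(pv$pseudocount)),
    sprintf("# orientation_sign\t%s", format(pv$orientation_sign)),
    sprintf("# version\t%s", .epVersion()),
    "aa\tn_in\tn_out\te_star"), con)
  df <- energyTable(table)
  writeLines(sprintf("%s\t%d\t%d\t%.10g", df$aa, df$n_in, df$n_out,
                     df$e_star), con)
  invisible(file)
}

#' Read a pseudoenergy table from TSV
#'
#' @param file path to a TSV written by [writeStats()] (extra `#` comment
#'   lines are ignored)
#' @return a [PseudoEnergyTable-class]
#' @export
readStats <- function(file) {
  if (!file.exists(file)) stop("no such stats file: ", file)
  lines <- readLines(file)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  getMeta <- function(key, default = NA) {
    hit <- grep(paste0("^#\\s*", key, "\\t"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\t"), "", hit[1]))
  }
  if (length(body) < 2L) stop("malformed stats file: no data rows")
  header <- strsplit(body[1], "\t")[[1]]
  if (!identical(header[1:4], c("aa", "n_in", "n_out", "e_star")))
    stop("malformed stats file: unexpected column header")
  df <- utils::read.table(text = paste(body[-1], collapse = "\n"),
                          sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("aa", "n_in", "n_out", "e_star"))
  if (nrow(df) != 20L || !identical(sort(df$aa), aminoAcids()))
    stop("malformed stats file: expected exactly the 20 canonical amino acids")
  methods::new("PseudoEnergyTable", table = df,
               provenance = list(
                 source_set = getMeta("source_set", "unknown"),
                 radius = as.numeric(getMeta("radius", "NA")),
                 pseudocount = as.numeric(getMeta("pseudocount", "NA")),
                 orientation_sign = as.numeric(getMeta("orientation_sign", "1")),
                 created = getMeta("version", "unknown")))
}

#' Bundled synthetic pseudoenergy table
#'
#' Loads the pseudoenergy table shipped with the package. This table is
#' SYNTHETIC: it was computed with [accumulateCounts()] over a seeded set of
#' generated structures in which each amino acid's buried probability
#' follows a logistic transform of Kyte-Doolittle hydropathy (see the
#' methods vignette). It exercises every pipeline stage with a realistic
#' energy spread, but it is not derived from experimental membrane-protein
#' structures; compute and supply your own statistics for biological
#' conclusions, and do not mix statistics across structure classes.
#'
#' @return a [PseudoEnergyTable-class]
#' @export
#' @examples
#' defaultEnergyTable()
defaultEnergyTable <- function() {
  readStats(system.file("extdata", "synthetic_stats.tsv",
                        package = "eprofiler", mustWork = TRUE))
}
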