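# Seeded synthetic structure and profile generators. These emulate the
# geometric regimes the energy model targets (alpha-helical traces, compact
# globules) and provide a controlled-buriedness design for Monte-Carlo
# recovery of the pseudoenergy formula; they make every pipeline stage
# testable without external structure sets. They are pure functions of
# their arguments and seed.

.sampleAA <- function(n, composition = NULL) {
  aas <- aminoAcids()
  if (is.null(composition)) composition <- stats::setNames(rep(1 / 20, 20), aas)
  stopifnot(abs(sum(composition) - 1) < 1e-6)
  sample(names(composition), n, replace = TRUE, prob = composition)
}

.newResidues <- function(aa, ca, cb, chain = "A") {
  data.frame(chain = chain, resno = seq_along(aa), ins = "", aa = aa,
             ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
             cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
             cb_virtual = FALSE, stringsAsFactors = FALSE)
}

#' Generate an ideal alpha-helical structure
#'
#' C-alpha trace on an ideal alpha-helix (radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees per residue; consecutive C-alpha distance about
#' 3.8 A) with the C-beta placed 1.53 A radially outward. Optional Gaussian
#' coordinate jitter.
#'
#' @param n number of residues (>= 1)
#' @param seed RNG seed (amino-acid sampling and jitter)
#' @param jitterSd standard deviation of isotropic Gaussian coordinate
#'   noise in Angstrom (default 0)
#' @param composition named amino-acid probabilities (default uniform)
#' @param id structure identifier
#' @return an [EPStructure-class]
#' @export
#' @examples
#' makeHelix(25, seed = 1)
makeHelix <- function(n, seed = 1L, jitterSd = 0, composition = NULL,
                      id = sprintf("helix_n%d_s%d", n, seed)) {
  stopifnot(n >= 1L, jitterSd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  r <- 2.3; rise <- 1.5
  ca <- cbind(r * cos(theta), r * sin(theta), rise * i)
  outward <- cbind(cos(theta), sin(theta), 0)
  cb <- ca + 1.53 * outward
  aa <- .sampleAA(n, composition)
  if (jitterSd > 0) {
    ca <- ca + matrix(stats::rnorm(3 * n, sd = jitterSd), n, 3)
    cb <- cb + matrix(stats::rnorm(3 * n, sd = jitterSd), n, 3)
  }
  EPStructure(id, .newResidues(aa, ca, cb))
}

#' Generate a compact globular structure
#'
#' Self-avoiding compact C-alpha arrangement: lattice points with `spacing`
#' (default 3.8 A) are taken in order of distance from the origin, giving a
#' roughly spherical blob. The C-beta of each residue points toward
#' (`cbOrientation = "in"`) or away from (`"out"`) the structure centroid;
#' a per-residue character vector may mix the two.
#'
#' @param n number of residues (>= 1)
#' @param seed RNG seed (amino-acid sampling and jitter)
#' @param spacing lattice constant in Angstrom (default 3.8)
#' @param cbOrientation "out" (default), "in", or a length-n vector of the
#'   two
#' @param jitterSd Gaussian coordinate noise sd in Angstrom (default 0)
#' @param composition named amino-acid probabilities (default uniform)
#' @param id structure identifier
#' @return an [EPStructure-class]
#' @export
makeGlobule <- function(n, seed = 1L, spacing = 3.8, cbOrientation = "out",
                        jitterSd = 0, composition = NULL,
                        id = sprintf("globule_n%d_s%d", n, seed)) {
  stopifnot(n >= 1L, spacing > 0, jitterSd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # lattice shell large enough to contain n points
  m <- 1L
  while ((2 * m + 1)^3 < n) m <- m + 1L
  g <- expand.grid(x = -m:m, y = -m:m, z = -m:m)
  d2 <- g$x^2 + g$y^2 + g$z^2
  ord <- order(d2, g$x, g$y, g$z)  # deterministic
  pts <- as.matrix(g[ord[seq_len(n)], ]) * spacing
  dimnames(pts) <- NULL
  centroid <- colMeans(pts)
  if (length(cbOrientation) == 1L) cbOrientation <- rep(cbOrientation, n)
  stopifnot(length(cbOrientation) == n, all(cbOrientation %in% c("in", "out")))
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    v <- centroid - pts[i, ]
    if (.vnorm(v) < 1e-9) v <- c(0, 0, 1)  # residue at the centroid
    u <- .unit(v)
    if (cbOrientation[i] == "out") u <- -u
    cb[i, ] <- pts[i, ] + 1.53 * u
  }
  aa <- .sampleAA(n, composition)
  if (jitterSd > 0) {
    pts <- pts + matrix(stats::rnorm(3 * n, sd = jitterSd), n, 3)
    cb <- cb + matrix(stats::rnorm(3 * n, sd = jitterSd), n, 3)
  }
  EPStructure(id, .newResidues(aa, pts, cb))
}

#' Generate isolated residue pairs with controlled buriedness
#'
#' The Monte-Carlo design for recovering pseudoenergies: residues are placed
#' in isolated pairs separated by exactly `radius` Angstrom (pairs are far
#' apart from each other), so each residue's local C-alpha centroid is its
#' partner, sitting exactly at the classification radius where the strict
#' distance criterion does not fire and the side-chain orientation term
#' alone decides the inside/outside call. Each residue's C-beta points
#' toward its partner with the buried probability of its amino acid; under
#' `orientationSign = -1` (side-chain-toward-center convention) such a
#' residue is classified inside. The recovered pseudoenergy of amino acid X
#' with buried probability p converges to -ln(p / (1 - p)).
#'
#' @param nPairs number of residue pairs
#' @param buriedProb either a single probability applied to all amino acids
#'   or a named vector per one-letter code
#' @param radius pair separation = classification radius (default 5)
#' @param seed RNG seed
#' @param composition named amino-acid probabilities (default uniform)
#' @param id structure identifier
#' @return an [EPStructure-class]
#' @export
makeBuriedPairs <- function(nPairs, buriedProb = 0.5, radius = 5, seed = 1L,
                            composition = NULL,
                            id = sprintf("pairs_n%d_s%d", nPairs, seed)) {
  stopifnot(nPairs >= 1L, radius > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2L * nPairs
  aa <- .sampleAA(n, composition)
  p <- if (length(buriedProb) == 1L && is.null(names(buriedProb)))
    stats::setNames(rep(buriedProb, 20), aminoAcids()) else buriedProb
  stopifnot(all(aminoAcids() %in% names(p)))
  # pair k sits at x = k * 10 * radius; partners split along y
  ca <- matrix(0, n, 3)
  cb <- matrix(0, n, 3)
  for (k in seq_len(nPairs)) {
    i <- 2L * k - 1L; j <- 2L * k
    base <- c(k * 10 * radius, 0, 0)
    ca[i, ] <- base
    ca[j, ] <- base + c(0, radius, 0)
    for (idx in c(i, j)) {
      partner <- if (idx == i) ca[j, ] else ca[i, ]
      toPartner <- .unit(partner - ca[idx, ])
      buried <- stats::runif(1) < p[[aa[idx]]]
      u <- if (buried) toPartner else -toPartner
      cb[idx, ] <- ca[idx, ] + 1.53 * u
    }
  }
  EPStructure(id, .newResidues(aa, ca, cb))
}

#' Rigid-body coordinate jitter of a structure
#'
#' Adds seeded isotropic Gaussian noise to all C-alpha and C-beta
#' coordinates. Useful for probing how dScore responds to small structural
#' perturbations.
#'
#' @param structure an [EPStructure-class]
#' @param sd noise standard deviation in Angstrom
#' @param seed RNG seed
#' @return a perturbed [EPStructure-class]
#' @export
jitterStructure <- function(structure, sd, seed = 1L) {
  stopifnot(sd >= 0)
  if (sd == 0) return(structure)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  df <- residueTable(structure)
  n <- nrow(df)
  df[, c("ca_x", "ca_y", "ca_z")] <-
    df[, c("ca_x", "ca_y", "ca_z")] + matrix(stats::rnorm(3 * n, sd = sd), n, 3)
  hasCb <- !is.na(df$cb_x)
  if (any(hasCb)) {
    nc <- sum(hasCb)
    df[hasCb, c("cb_x", "cb_y", "cb_z")] <-
      df[hasCb, c("cb_x", "cb_y", "cb_z")] +
      matrix(stats::rnorm(3 * nc, sd = sd), nc, 3)
  }
  EPStructure(paste0(structureId(structure), "_jit"), df)
}

#' Add Gaussian noise to a profile's energies
#'
#' @param profile an [EnergyProfile-class]
#' @param sd noise standard deviation in a.u. (0 = identity)
#' @param seed RNG seed
#' @return a perturbed [EnergyProfile-class]
#' @export
perturbProfile <- function(profile, sd, seed = 1L) {
  stopifnot(sd >= 0)
  if (sd == 0) return(profile)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  df <- profileEntries(profile)
  df$energy <- df$energy + stats::rnorm(nrow(df), sd = sd)
  methods::new("EnergyProfile", id = paste0(profile@id, "_pert"),
               entries = df, statsProvenance = profile@statsProvenance,
               contactRadius = profile@contactRadius)
}

# buried probability per amino acid used for the bundled synthetic table:
# logistic transform of Kyte-Doolittle hydropathy, p = 1/(1 + exp(-KD/2)),
# so hydrophobic residues are buried more often and e* is approx -KD/2
.syntheticBuriedProbs <- function() {
  stats::setNames(1 / (1 + exp(-.KYTE_DOOLITTLE / 2)),
                  names(.KYTE_DOOLITTLE))
}

#' Recompute the bundled synthetic pseudoenergy table
#'
#' Deterministically regenerates the statistics behind
#' [defaultEnergyTable()]: 500 isolated residue pairs per amino acid
#' ([makeBuriedPairs()]) with buried probabilities following a logistic
#' transform of Kyte-Doolittle hydropathy, classified at radius 5 under
#' the side-chain-toward-center convention and converted with pseudocount 1.
#'
#' @param seed RNG seed (default 20120315)
#' @param pairsPerAA residue pairs generated per amino acid (default 500)
#' @return a [PseudoEnergyTable-class]
#' @export
syntheticEnergyTable <- function(seed = 20120315L, pairsPerAA = 500L) {
  probs <- .syntheticBuriedProbs()
  structs <- lapply(seq_along(aminoAcids()), function(k) {
    a <- aminoAcids()[k]
    comp <- stats::setNames(rep(0, 20), aminoAcids())
    comp[a] <- 1
    makeBuriedPairs(pairsPerAA, buriedProb = probs, radius = 5,
                    seed = seed + k, composition = comp,
                    id = paste0("synth_", a))
  })
  counts <- accumulateCounts(structs, radius = 5, orientationSign = -1,
                             sourceSet = "synthetic-kd-logistic")
  pseudoEnergies(counts, pseudocount = 1)
}
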