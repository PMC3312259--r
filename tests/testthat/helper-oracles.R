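# Independent oracles and fixture builders shared across tests.

# profile with given energies (uniform dummy metadata)
toyProfile <- function(e, id = "toy", aa = NULL) {
  n <- length(e)
  if (is.null(aa)) aa <- rep("A", n)
  new("EnergyProfile", id = id,
      entries = data.frame(chain = "A", resno = seq_len(n), aa = aa,
                           energy = e, stringsAsFactors = FALSE),
      statsProvenance = "toy", contactRadius = 8)
}

# pseudoenergy table with explicit e* values (counts are placeholders)
toyTable <- function(eStar) {
  aas <- aminoAcids()
  ev <- rep(0, 20); names(ev) <- aas
  ev[names(eStar)] <- eStar
  new("PseudoEnergyTable",
      table = data.frame(aa = aas, n_in = 0L, n_out = 0L,
                         e_star = unname(ev), stringsAsFactors = FALSE),
      provenance = list(source_set = "toy", radius = 5, pseudocount = 1,
                        orientation_sign = 1, created = "test"))
}

# structure from bare coordinate matrices
toyStructure <- function(ca, aa = NULL, cb = NULL, id = "toy") {
  n <- nrow(ca)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3)
  EPStructure(id, data.frame(
    chain = "A", resno = seq_len(n), ins = "", aa = aa,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
    cb_virtual = FALSE, stringsAsFactors = FALSE))
}

# exhaustive global alignment score: plain recursion over all move paths,
# no memoization or DP sharing
bruteGlobalScore <- function(S, gap) {
  m <- nrow(S); n <- ncol(S)
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) best <- max(best, rec(i - 1L, j - 1L) + S[i, j])
    if (i > 0L) best <- max(best, rec(i - 1L, j) - gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) - gap)
    best
  }
  rec(m, n)
}

# exhaustive local alignment score: best global score over all substring
# pairs, floored at zero (the empty alignment)
bruteLocalScore <- function(S, gap) {
  m <- nrow(S); n <- ncol(S)
  best <- 0
  for (i1 in seq_len(m)) for (i2 in i1:m)
    for (j1 in seq_len(n)) for (j2 in j1:n)
      best <- max(best, bruteGlobalScore(S[i1:i2, j1:j2, drop = FALSE], gap))
  best
}

# naive O(n^2) double-loop energy profile
naiveProfileEnergies <- function(structure, table, cutoff = 8) {
  ca <- caCoords(structure)
  aa <- residueTable(structure)$aa
  e <- energyFor(table, aa)
  n <- nrow(ca)
  E <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((ca[i, ] - ca[j, ])^2)) <= cutoff) E[i] <- E[i] + e[i] + e[j]
    }
  }
  E
}

# reference UPGMA: cluster distances recomputed from the ORIGINAL matrix as
# the mean over all cross pairs at every step (no incremental update);
# returns the sequence of merged label sets and merge distances
bruteUpgma <- function(D) {
  labels <- rownames(D)
  clusters <- lapply(seq_along(labels), function(i) i)
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(d = d, i = i, j = j, lab = lab)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- sort(labels[merged])
    heights <- c(heights, best$d)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(merges = merges, heights = heights)
}

# merged label sets in merge order for a GuideTree
treeMergeSets <- function(tree) {
  sets <- vector("list", nrow(tree@merge))
  grab <- function(id) {
    if (id < 0L) tree@labels[-id] else sets[[id]]
  }
  for (r in seq_len(nrow(tree@merge))) {
    sets[[r]] <- sort(c(grab(tree@merge[r, 1]), grab(tree@merge[r, 2])))
  }
  sets
}

# random rigid-body transform applied to a structure
rigidTransform <- function(structure, seed = 1) {
  set.seed(seed)
  # random rotation via QR of a random matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, sd = 20)
  df <- residueTable(structure)
  ca <- as.matrix(df[, c("ca_x", "ca_y", "ca_z")]) %*% t(R)
  df[, c("ca_x", "ca_y", "ca_z")] <- sweep(ca, 2, -tr)
  hasCb <- !is.na(df$cb_x)
  if (any(hasCb)) {
    cb <- as.matrix(df[hasCb, c("cb_x", "cb_y", "cb_z")]) %*% t(R)
    df[hasCb, c("cb_x", "cb_y", "cb_z")] <- sweep(cb, 2, -tr)
  }
  EPStructure(paste0(structureId(structure), "_rt"), df)
}
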