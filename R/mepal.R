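# Multiple energy profile alignment (MEPAL).
#
# 1. all-vs-all pairwise dScores -> distance matrix
# 2. UPGMA agglomeration with recorded merge order (lexicographic ties)
# 3. progressive alignment along the merge order, scoring profile-vs-group
#    columns by the mean pairwise energy score over non-gap members
# 4. per-column consensus energy (member maximizing summed pair scores)
#    and conservation (summed pair scores / best possible sum).

#' All-vs-all dScore distance matrix
#'
#' Aligns every pair of profiles with [alignProfiles()] and collects the
#' dScores into a symmetric matrix with zero diagonal.
#'
#' @param profiles list of [EnergyProfile-class] with unique ids
#' @param ... passed on to [alignProfiles()] (mode, nBins, sMax, gap,
#'   nPerm, seed, binner, ...)
#' @return symmetric numeric matrix with profile ids as dimnames
#' @export
distanceMatrix <- function(profiles, ...) {
  k <- length(profiles)
  stopifnot(k >= 2L)
  ids <- vapply(profiles, function(p) p@id, character(1))
  if (anyDuplicated(ids)) stop("profile ids must be unique")
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      res <- tryCatch(alignProfiles(profiles[[i]], profiles[[j]], ...),
                      error = function(e)
                        stop("pairwise alignment failed for '", ids[i],
                             "' vs '", ids[j], "': ", conditionMessage(e)))
      D[i, j] <- D[j, i] <- dScore(res)
    }
  }
  D
}

#' UPGMA guide tree from a distance matrix
#'
#' Unweighted pair-group agglomeration with arithmetic mean: repeatedly
#' merges the closest pair of clusters; the distance of a merged cluster to
#' any other is the size-weighted mean of its parts (equivalently, the mean
#' of all cross pairs of the original matrix). Ties are broken by the
#' lexicographic order of cluster labels (a cluster is labelled by its
#' lexicographically smallest member). Merge order is recorded for the
#' progressive alignment.
#'
#' @param D symmetric distance matrix with dimnames (no NAs)
#' @return a [GuideTree-class]
#' @export
upgmaTree <- function(D) {
  if (is.null(dimnames(D)[[1]])) stop("distance matrix needs dimnames")
  if (anyNA(D)) stop("distance matrix contains NA")
  labels <- rownames(D)
  n <- length(labels)
  stopifnot(n >= 2L, all(abs(D - t(D)) < 1e-12))
  member <- as.list(-seq_len(n))        # hclust-style ids
  clabel <- labels                      # lexicographic tie-break label
  size <- rep(1L, n)
  W <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node <- 0L
  for (step in seq_len(n - 1L)) {
    k <- nrow(W)
    # find min distance; ties -> lexicographically smallest (labelA, labelB)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        lab <- sort(c(clabel[i], clabel[j]))
        cand <- list(d = W[i, j], i = i, j = j, lab = lab)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    node <- node + 1L
    merge[node, ] <- c(member[[i]][1], member[[j]][1])
    height[node] <- best$d
    if (step < n - 1L) {
      # weighted-average update = mean over original cross pairs
      newrow <- (size[i] * W[i, ] + size[j] * W[j, ]) / (size[i] + size[j])
      keep <- setdiff(seq_len(k), c(i, j))
      W <- rbind(cbind(W[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
      member <- c(member[keep], list(node))
      clabel <- c(clabel[keep], min(clabel[c(i, j)]))
      size <- c(size[keep], size[i] + size[j])
    }
  }
  # hclust merge convention stores node ids directly; ours already match
  methods::new("GuideTree", labels = labels, merge = merge, height = height)
}

#' Convert a guide tree to hclust / phylo
#'
#' @param tree a [GuideTree-class]
#' @return `asHclust`: a `stats::hclust` object; `asPhylo`: an `ape::phylo`
#'   ultrametric tree (leaf depth = merge distance / 2).
#' @export
asHclust <- function(tree) {
  structure(list(merge = tree@merge, height = tree@height,
                 order = .treeLeafOrder(tree), labels = tree@labels,
                 method = "average", call = match.call(),
                 dist.method = "dScore"),
            class = "hclust")
}

#' @rdname asHclust
#' @export
asPhylo <- function(tree) {
  ape::as.phylo(asHclust(tree))
}

#' Write a guide tree in Newick format
#'
#' @param tree a [GuideTree-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeGuideTree <- function(tree, file) {
  ape::write.tree(asPhylo(tree), file = file)
  invisible(file)
}

# leaf order for plotting: left-to-right traversal of the merge matrix
.treeLeafOrder <- function(tree) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(tree@merge[node, 1]), rec(tree@merge[node, 2]))
  }
  rec(nrow(tree@merge))
}

# group = list(ids, energy k x L matrix with NA gaps, aa k x L)
.profileAsGroup <- function(p) {
  df <- profileEntries(p)
  list(ids = p@id,
       energy = matrix(df$energy, nrow = 1L),
       aa = matrix(df$aa, nrow = 1L))
}

# mean pairwise energy score between two group columns over non-gap members
.groupScoreMatrix <- function(binsA, binsB, sMax) {
  LA <- ncol(binsA); LB <- ncol(binsB)
  S <- matrix(0, LA, LB)
  for (u in seq_len(LA)) {
    ca <- binsA[, u]
    ca <- ca[!is.na(ca)]
    for (v in seq_len(LB)) {
      cb <- binsB[, v]
      cb <- cb[!is.na(cb)]
      S[u, v] <- sMax - mean(abs(outer(ca, cb, "-")))
    }
  }
  S
}

.mergeGroups <- function(gA, gB, binner, sMax, gap) {
  binsA <- matrix(binOf(binner, gA$energy), nrow = nrow(gA$energy))
  binsB <- matrix(binOf(binner, gB$energy), nrow = nrow(gB$energy))
  binsA[is.na(gA$energy)] <- NA; binsB[is.na(gB$energy)] <- NA
  S <- .groupScoreMatrix(binsA, binsB, sMax)
  H <- .dpMatrix(S, gap, local = FALSE)
  pairs <- .traceback(H, S, gap, local = FALSE)
  kA <- nrow(gA$energy); kB <- nrow(gB$energy)
  L <- nrow(pairs)
  energy <- matrix(NA_real_, kA + kB, L)
  aa <- matrix(NA_character_, kA + kB, L)
  for (col in seq_len(L)) {
    a <- pairs[col, 1]; b <- pairs[col, 2]
    if (!is.na(a)) {
      energy[1:kA, col] <- gA$energy[, a]
      aa[1:kA, col] <- gA$aa[, a]
    }
    if (!is.na(b)) {
      energy[(kA + 1):(kA + kB), col] <- gB$energy[, b]
      aa[(kA + 1):(kA + kB), col] <- gB$aa[, b]
    }
  }
  list(ids = c(gA$ids, gB$ids), energy = energy, aa = aa)
}

#' Consensus energy of an alignment column
#'
#' Among the column's non-gap member energies, returns the one maximizing
#' the sum of pairwise energy scores to all other members; ties are broken
#' toward the lower energy.
#'
#' @param column numeric vector of member energies (NA = gap)
#' @param binner an [EnergyBinner-class]
#' @param sMax maximal pair score
#' @return numeric(1) consensus energy
#' @export
consensusEnergy <- function(column, binner, sMax = binner@nBins) {
  e <- column[!is.na(column)]
  if (length(e) == 0L) stop("all-gap column has no consensus")
  if (length(e) == 1L) return(e)
  bins <- binOf(binner, e)
  sums <- vapply(seq_along(e), function(i)
    sum(sMax - abs(bins[i] - bins[-i])), numeric(1))
  cand <- e[sums == max(sums)]
  min(cand)
}

#' Conservation of an alignment column
#'
#' Sum of all pairwise energy scores among the column's non-gap members,
#' normalized by the best possible sum (number of pairs times delta = sMax).
#' Columns with a single member report 1.0 by convention (configurable).
#'
#' @inheritParams consensusEnergy
#' @param singleValue value reported for single-member columns (default 1.0;
#'   set to NA to mark them as not assessable)
#' @return numeric(1) in `[0, 1]` (or `singleValue`)
#' @export
conservationOf <- function(column, binner, sMax = binner@nBins,
                           singleValue = 1.0) {
  e <- column[!is.na(column)]
  if (length(e) == 0L) stop("all-gap column has no conservation")
  if (length(e) == 1L) return(singleValue)
  bins <- binOf(binner, e)
  pr <- utils::combn(length(e), 2L)
  sc <- sMax - abs(bins[pr[1, ]] - bins[pr[2, ]])
  sum(sc) / (ncol(pr) * sMax)
}

#' Progressive multiple energy profile alignment
#'
#' Merges profiles in guide-tree order using the same dynamic programming
#' as the pairwise alignment; group columns are scored by the mean pairwise
#' energy score over non-gap members, and gaps introduced in earlier merges
#' are preserved ("once a gap, always a gap"). The binner is fitted once on
#' the pooled energies of all profiles.
#'
#' @param profiles list of [EnergyProfile-class]
#' @param tree a [GuideTree-class] whose leaves are the profile ids
#' @param nBins number of energy bins (default 20)
#' @param sMax maximal pair score (default nBins)
#' @param gap linear gap penalty (default sMax/2)
#' @param binner optional fixed [EnergyBinner-class]
#' @param singleValue conservation reported for single-member columns
#' @return a [ProfileMSA-class]
#' @export
progressiveAlign <- function(profiles, tree, nBins = 20L, sMax = nBins,
                             gap = sMax / 2, binner = NULL,
                             singleValue = 1.0) {
  ids <- vapply(profiles, function(p) p@id, character(1))
  if (!setequal(ids, tree@labels))
    stop("guide tree leaves must match profile ids")
  if (is.null(binner))
    binner <- buildBinner(unlist(lapply(profiles, energies)), nBins)
  groups <- vector("list", nrow(tree@merge))
  leaf <- function(j) .profileAsGroup(profiles[[match(tree@labels[j], ids)]])
  for (node in seq_len(nrow(tree@merge))) {
    a <- tree@merge[node, 1]; b <- tree@merge[node, 2]
    gA <- if (a < 0L) leaf(-a) else groups[[a]]
    gB <- if (b < 0L) leaf(-b) else groups[[b]]
    groups[[node]] <- .mergeGroups(gA, gB, binner, sMax, gap)
  }
  g <- groups[[nrow(tree@merge)]]
  cons <- apply(g$energy, 2L, consensusEnergy, binner = binner, sMax = sMax)
  cval <- apply(g$energy, 2L, conservationOf, binner = binner, sMax = sMax,
                singleValue = singleValue)
  methods::new("ProfileMSA", ids = g$ids, energy = g$energy, aa = g$aa,
               consensus = cons, conservation = cval, binner = binner,
               sMax = sMax)
}

#' Multiple energy profile alignment (MEPAL)
#'
#' Convenience wrapper: computes the all-vs-all dScore matrix, the UPGMA
#' guide tree and the progressive alignment with consensus and conservation.
#'
#' @param profiles list of at least two [EnergyProfile-class]
#' @param mode pairwise alignment mode for the distance matrix
#' @param nBins,sMax,gap scoring parameters (see [alignProfiles()])
#' @param nPerm,seed permutation calibration of the pairwise dScores
#' @param ... further arguments to [alignProfiles()]
#' @return list with elements `distances` (matrix), `tree`
#'   ([GuideTree-class]) and `msa` ([ProfileMSA-class])
#' @export
#' @examples
#' tab <- defaultEnergyTable()
#' ps <- lapply(1:3, function(k)
#'   computeProfile(makeHelix(30, seed = k), tab, id = paste0("h", k)))
#' res <- mepal(ps, nPerm = 20)
#' res$msa
mepal <- function(profiles, mode = "global", nBins = 20L, sMax = nBins,
                  gap = sMax / 2, nPerm = 100L, seed = 42L, ...) {
  D <- distanceMatrix(profiles, mode = mode, nBins = nBins, sMax = sMax,
                      gap = gap, nPerm = nPerm, seed = seed, ...)
  tree <- upgmaTree(D)
  msa <- progressiveAlign(profiles, tree, nBins = nBins, sMax = sMax,
                          gap = gap)
  list(distances = D, tree = tree, msa = msa)
}

#' Render a multiple alignment as a text report
#'
#' Three blocks per line-wrapped segment: (1) per-profile rows of one-letter
#' amino-acid codes with, underneath, the energy bin of each column entry
#' encoded as a letter `a`-`t` (bin 1-20); (2) the consensus row (bins of
#' the consensus energies); (3) the conservation track, `0`-`9` glyphs
#' scaling 0 to 1. Gaps are rendered as `-`. Deterministic.
#'
#' @param msa a [ProfileMSA-class]
#' @param width columns per segment (default 60)
#' @return character vector of report lines
#' @export
renderMepal <- function(msa, width = 60L) {
  L <- ncol(msa@energy)
  k <- length(msa@ids)
  binChar <- function(b) letters[pmin(b, 20L)]
  consBins <- binOf(msa@binner, msa@consensus)
  glyph <- as.character(pmin(9L, floor(msa@conservation * 10)))
  glyph[msa@conservation >= 1] <- "9"
  nameW <- max(nchar(c(msa@ids, "consensus", "conserv.")))
  pad <- function(s) formatC(s, width = nameW, flag = "-")
  out <- c(sprintf("MEPAL report: %d profiles, %d columns", k, L),
           sprintf("(eprofiler %s)", .epVersion()), "")
  starts <- seq(1L, L, by = width)
  for (st in starts) {
    en <- min(st + width - 1L, L)
    idx <- st:en
    out <- c(out, sprintf("columns %d-%d", st, en))
    for (r in seq_len(k)) {
      aarow <- msa@aa[r, idx]
      aarow[is.na(aarow)] <- "-"
      bins <- rep("-", length(idx))
      nz <- !is.na(msa@energy[r, idx])
      bins[nz] <- binChar(binOf(msa@binner, msa@energy[r, idx][nz]))
      out <- c(out,
               paste0(pad(msa@ids[r]), " ", paste(aarow, collapse = "")),
               paste0(pad(""), " ", paste(bins, collapse = "")))
    }
    out <- c(out,
             paste0(pad("consensus"), " ",
                    paste(binChar(consBins[idx]), collapse = "")),
             paste0(pad("conserv."), " ", paste(glyph[idx], collapse = "")),
             "")
  }
  out
}
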