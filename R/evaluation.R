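# Validation procedures: profile fragmentation, neural-gas clustering,
# normalized mutual information, Spearman rank correlation.

#' Fragment energy profiles into fixed-length windows
#'
#' Slides a window of `window` residues along each profile (step 1) and
#' labels each fragment with the externally supplied category of its center
#' residue. Labels play no role in clustering; they are held out for
#' evaluation only. Profiles shorter than the window are skipped with a
#' warning.
#'
#' @param profiles list of [EnergyProfile-class]
#' @param window fragment length in residues (default 5)
#' @param labels data.frame with columns `profile`, `index` (1-based residue
#'   position within the profile) and `label`; must cover all residues of
#'   the supplied profiles
#' @return list with `windows` (fragments x window numeric matrix of
#'   energies), and `meta` (data.frame: `profile`, `start`, `label`)
#' @export
fragmentProfiles <- function(profiles, window = 5L, labels) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  stopifnot(all(c("profile", "index", "label") %in% names(labels)))
  rows <- list(); metas <- list()
  for (p in profiles) {
    n <- length(p)
    if (n < window) {
      warning("profile '", p@id, "' shorter than window; skipped")
      next
    }
    lab <- labels[labels$profile == p@id, , drop = FALSE]
    resLab <- lab$label[match(seq_len(n), lab$index)]
    if (anyNA(resLab))
      stop("labels do not cover all residues of profile '", p@id, "'")
    e <- energies(p)
    starts <- seq_len(n - window + 1L)
    center <- starts + (window - 1L) %/% 2L
    rows[[length(rows) + 1L]] <-
      t(vapply(starts, function(s) e[s:(s + window - 1L)], numeric(window)))
    metas[[length(metas) + 1L]] <-
      data.frame(profile = p@id, start = starts, label = resLab[center],
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no profile long enough for the window")
  list(windows = do.call(rbind, rows), meta = do.call(rbind, metas))
}

#' Neural-gas clustering
#'
#' Standard neural-gas prototype adaptation: at each step a random sample is
#' presented, prototypes are ranked by Euclidean distance, and every
#' prototype w_r moves by eps(t) * exp(-rank/lambda(t)) * (x - w_r), with
#' exponentially decaying learning rate eps and neighborhood range lambda.
#' The final assignment maps each point to its nearest prototype.
#'
#' @param x numeric matrix, points x dimensions
#' @param k number of prototypes (>= 1; k > 1 for a non-trivial clustering)
#' @param iterations total adaptation steps (default 100 per prototype)
#' @param seed RNG seed
#' @param epsStart,epsEnd initial/final learning rate (defaults 0.5, 0.005)
#' @param lambdaStart,lambdaEnd initial/final neighborhood range (defaults
#'   k/2, 0.01)
#' @return list with `assignment` (integer vector in 1..k) and `prototypes`
#'   (k x dimensions matrix)
#' @export
neuralGas <- function(x, k, iterations = 100L * k, seed = 1L,
                      epsStart = 0.5, epsEnd = 0.005,
                      lambdaStart = k / 2, lambdaEnd = 0.01) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k >= 1L)
  if (k > n) stop("more prototypes than data points")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- x[sample.int(n, k), , drop = FALSE]
  tmax <- max(1L, as.integer(iterations))
  for (t in seq_len(tmax)) {
    frac <- (t - 1) / max(1, tmax - 1)
    eps <- epsStart * (epsEnd / epsStart)^frac
    lambda <- lambdaStart * (lambdaEnd / lambdaStart)^frac
    xi <- x[sample.int(n, 1L), ]
    d <- sqrt(rowSums((W - matrix(xi, k, ncol(W), byrow = TRUE))^2))
    rank <- rank(d, ties.method = "first") - 1
    h <- eps * exp(-rank / lambda)
    W <- W + h * (matrix(xi, k, ncol(W), byrow = TRUE) - W)
  }
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(W) +
    outer(rep(1, n), rowSums(W^2))
  assignment <- max.col(-d2, ties.method = "first")
  list(assignment = assignment, prototypes = W)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two
#' entropies (default), I(A;B) / ((H(A)+H(B))/2); variants normalize by the
#' minimum, maximum or geometric mean. 1 for identical partitions; 0 when
#' either partition is constant or the partitions are independent.
#'
#' @param a,b vectors of equal length with categorical labels
#' @param normalization one of "arithmetic", "min", "max", "geometric"
#' @return numeric(1) in `[0, 1]`
#' @export
nmi <- function(a, b, normalization = c("arithmetic", "min", "max",
                                        "geometric")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) == 0L) stop("labelings must be non-empty")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pi_); hb <- ent(pj_)
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb),
                  geometric = sqrt(ha * hb))
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}

#' Repeated neural-gas clustering with held-out labels
#'
#' Per repeat, resamples `sampleSize` fragments (without replacement if
#' possible), clusters them with [neuralGas()] while ignoring the labels,
#' and scores the assignment against the held-out labels with [nmi()].
#'
#' @param fragments result of [fragmentProfiles()] (list with `windows`
#'   and `meta`)
#' @param k number of prototypes (default: number of distinct labels)
#' @param iterations adaptation steps per repeat (default 100 per prototype)
#' @param repeats number of repeats (default 100)
#' @param sampleSize fragments drawn per repeat (default 600)
#' @param seed master RNG seed
#' @param normalization passed to [nmi()]
#' @return list with `nmi` (per-repeat values), `mean` and `sd`
#' @export
repeatClustering <- function(fragments, k = NULL, iterations = NULL,
                             repeats = 100L, sampleSize = 600L, seed = 1L,
                             normalization = "arithmetic") {
  x <- fragments$windows
  lab <- fragments$meta$label
  if (is.null(k)) k <- length(unique(lab))
  if (is.null(iterations)) iterations <- 100L * k
  stopifnot(repeats >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, repeats)
  vals <- numeric(repeats)
  for (r in seq_len(repeats)) {
    idx <- if (nrow(x) > sampleSize) sample.int(nrow(x), sampleSize)
           else seq_len(nrow(x))
    ng <- neuralGas(x[idx, , drop = FALSE], k = k, iterations = iterations,
                    seed = subseeds[r])
    vals[r] <- nmi(ng$assignment, lab[idx], normalization = normalization)
  }
  list(nmi = vals, mean = mean(vals), sd = stats::sd(vals))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via `stats::cor`. Raises an
#' error for constant input (undefined correlation) instead of returning NA.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return numeric(1) rho in `[-1, 1]`
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  stats::cor(x, y, method = "spearman")
}
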