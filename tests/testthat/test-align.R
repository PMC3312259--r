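# Energy binning, dynamic-programming alignment and dScore calibration.

test_that("binner boundaries sit at the fitted normal quantiles", {
  set.seed(1)
  e <- rnorm(500, mean = 3, sd = 2)
  b2 <- buildBinner(e, nBins = 2)
  expect_equal(b2@boundaries, mean(e))          # median of a normal = mean
  b4 <- buildBinner(e, nBins = 4)
  expect_equal(b4@boundaries,
               qnorm(c(0.25, 0.5, 0.75), mean(e), sd(e)))  # quantile oracle
  # location equivariance
  b4s <- buildBinner(e + 10, nBins = 4)
  expect_equal(b4s@boundaries, b4@boundaries + 10, tolerance = 1e-9)
  expect_error(buildBinner(rep(1, 10)), "zero variance")
  expect_error(buildBinner(1.5), "at least two")
})

test_that("pair scores are symmetric bin distances below the maximum", {
  b <- buildBinner(rnorm(200), nBins = 20)
  expect_equal(pairScore(0.3, 0.3, b), 20)       # same energy: delta
  # energies straddling one boundary: adjacent bins, score 19
  lo <- b@boundaries[10] - 1e-6
  hi <- b@boundaries[10] + 1e-6
  expect_equal(pairScore(lo, hi, b), 19)
  expect_equal(pairScore(hi, lo, b), pairScore(lo, hi, b))
  # extreme energies clamp to the edge bins
  expect_equal(binOf(b, -1e6), 1L)
  expect_equal(binOf(b, 1e6), 20L)
})

test_that("self-alignment attains the theoretical optimum", {
  p <- computeProfile(makeHelix(40, seed = 1), defaultEnergyTable())
  b <- buildBinner(energies(p), nBins = 20)
  res <- globalAlign(p, p, b)
  expect_equal(res@xR, 20 * length(p))
  expect_equal(res@xR, res@xOpt)
  expect_equal(alignedPairs(res)[, "a"], seq_len(length(p)))
  expect_equal(alignedPairs(res)[, "b"], seq_len(length(p)))
  # single-entry profiles with equal energy align with x_r = delta
  one <- toyProfile(0.5)
  b1 <- buildBinner(c(0, 1), nBins = 20)
  expect_equal(globalAlign(one, toyProfile(0.5, id = "o2"), b1)@xR, 20)
})

test_that("DP scores equal exhaustive enumeration on short profiles", {
  set.seed(7)
  b <- buildBinner(rnorm(100), nBins = 20)
  for (rep in 1:40) {
    nA <- sample(1:5, 1); nB <- sample(1:5, 1)
    A <- toyProfile(rnorm(nA), id = "A")
    B <- toyProfile(rnorm(nB), id = "B")
    S <- outer(binOf(b, energies(A)), binOf(b, energies(B)),
               function(x, y) 20 - abs(x - y))
    gap <- sample(c(5, 10, 15), 1)
    expect_equal(globalAlign(A, B, b, gap = gap)@xR,
                 bruteGlobalScore(S, gap))
    expect_equal(localAlign(A, B, b, gap = gap)@xR,
                 bruteLocalScore(S, gap))
  }
})

test_that("aligned index sequences are valid and traceback score-consistent", {
  set.seed(8)
  b <- buildBinner(rnorm(100), nBins = 20)
  for (rep in 1:10) {
    A <- toyProfile(rnorm(sample(3:12, 1)), id = "A")
    B <- toyProfile(rnorm(sample(3:12, 1)), id = "B")
    res <- globalAlign(A, B, b)
    pr <- alignedPairs(res)
    # every residue of both profiles is consumed exactly once
    expect_equal(sort(pr[!is.na(pr[, "a"]), "a"]), seq_len(length(A)))
    expect_equal(sort(pr[!is.na(pr[, "b"]), "b"]), seq_len(length(B)))
    # recompute the score from the path
    sc <- 0
    for (r in seq_len(nrow(pr))) {
      if (is.na(pr[r, "a"]) || is.na(pr[r, "b"])) sc <- sc - 10
      else sc <- sc + pairScore(energies(A)[pr[r, "a"]],
                                energies(B)[pr[r, "b"]], b)
    }
    expect_equal(sc, res@xR)
  }
})

test_that("local alignment floors at the empty alignment", {
  b <- buildBinner(seq(-3, 3, length.out = 50), nBins = 20)
  A <- toyProfile(rep(-10, 6), id = "A")   # edge bin 1
  B <- toyProfile(rep(10, 6), id = "B")    # edge bin 20
  # sMax = 5 makes every pair score negative (5 - 19)
  res <- localAlign(A, B, b, sMax = 5, gap = 10)
  expect_equal(res@xR, 0)
  expect_equal(nrow(alignedPairs(res)), 0L)
  # identical profiles align full length locally
  resAA <- localAlign(A, A, b)
  expect_equal(resAA@xR, 20 * 6)
})

test_that("permutation means are reproducible, bounded and degenerate-safe", {
  p <- computeProfile(makeHelix(25, seed = 2), defaultEnergyTable())
  b <- buildBinner(energies(p), nBins = 20)
  m1 <- permutationMean(p, p, b, nPerm = 50, seed = 11)
  m2 <- permutationMean(p, p, b, nPerm = 50, seed = 11)
  expect_identical(m1, m2)
  expect_lte(m1, 20 * length(p))
  # single-entry profiles: permutation is the identity
  one <- toyProfile(0.2); two <- toyProfile(0.9, id = "t2")
  b1 <- buildBinner(c(0.2, 0.9), nBins = 4)
  expect_equal(permutationMean(one, two, b1, nPerm = 10, seed = 1),
               globalAlign(one, two, b1)@xR)
})

test_that("dScore maps the score interval onto bans", {
  expect_equal(dScoreValue(100, 100, 40), 0)
  expect_equal(dScoreValue(46, 100, 40), 1)        # ratio 0.1
  expect_equal(dScoreValue(40, 100, 40), 10)       # ratio 0: capped
  expect_equal(dScoreValue(10, 100, 40), 10)       # negative ratio: capped
  expect_equal(dScoreValue(70, 100, 40, cap = 5), -log10(0.5))
  expect_error(dScoreValue(50, 100, 100), "degenerate")
})

test_that("aligning a profile with itself yields exactly zero bans", {
  p <- computeProfile(makeHelix(60, seed = 1), defaultEnergyTable())
  res <- alignProfiles(p, p, seed = 42)
  expect_identical(dScore(res), 0)
  expect_true(isSignificant(res))
  res2 <- alignProfiles(p, p, seed = 43)  # permutation outcome irrelevant
  expect_identical(dScore(res2), 0)
})

test_that("alignment results are deterministic and symmetric", {
  tab <- defaultEnergyTable()
  A <- computeProfile(makeHelix(30, seed = 3), tab, id = "A")
  B <- computeProfile(makeHelix(34, seed = 4), tab, id = "B")
  r1 <- alignProfiles(A, B, seed = 5, nPerm = 60)
  r2 <- alignProfiles(A, B, seed = 5, nPerm = 60)
  expect_identical(dScore(r1), dScore(r2))
  expect_identical(alignedPairs(r1), alignedPairs(r2))
  rBA <- alignProfiles(B, A, seed = 5, nPerm = 60)
  expect_identical(dScore(rBA), dScore(r1))
  expect_identical(alignmentScores(rBA), alignmentScores(r1))
  expect_identical(alignedPairs(rBA)[, "a"], alignedPairs(r1)[, "b"])
})

test_that("shuffling a long profile destroys alignment significance", {
  # the raw score of a shuffled copy is itself a draw from the permutation
  # null, so its dScore is large but stochastic: assert the median over
  # replicates, not a single draw
  tab <- defaultEnergyTable()
  p <- computeProfile(makeHelix(80, seed = 6), tab, id = "p")
  d <- vapply(1:15, function(r) {
    set.seed(900 + r)
    q <- toyProfile(sample(energies(p)), id = "q")
    dScore(alignProfiles(p, q, seed = 7, nPerm = 60))
  }, numeric(1))
  expect_gt(median(d), 2.5)          # typically not significant
  expect_true(all(d > 0.5))          # never close to identity
})

test_that("median dScore grows with perturbation noise", {
  tab <- defaultEnergyTable()
  p <- computeProfile(makeHelix(40, seed = 10), tab, id = "base")
  sds <- c(0, 2, 8)
  med <- vapply(sds, function(sd) {
    d <- vapply(1:9, function(r) {
      q <- perturbProfile(p, sd, seed = 1000 * sd + r)
      dScore(alignProfiles(p, q, seed = 31, nPerm = 40))
    }, numeric(1))
    median(d)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_identical(med[1], 0)  # sd 0 is the identity
})
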