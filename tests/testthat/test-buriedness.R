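# Inside/outside classification and pseudoenergy derivation.

test_that("local center follows its definition on fixed geometries", {
  # isolated residue: no neighbors
  lone <- toyStructure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_null(localCenter(lone, 1, radius = 5))
  # one neighbor at (x+4, y, z): the center is that neighbor
  pair <- toyStructure(rbind(c(1, 2, 3), c(5, 2, 3)))
  expect_equal(localCenter(pair, 1, radius = 5), c(5, 2, 3))
  # three symmetric neighbors: the center is the residue's own position
  sym <- toyStructure(rbind(c(0, 0, 0),
                            c(4, 0, 0), c(-2, 2 * sqrt(3), 0),
                            c(-2, -2 * sqrt(3), 0)))
  expect_equal(localCenter(sym, 1, radius = 5), c(0, 0, 0),
               tolerance = 1e-12)
  # self-inclusion mode shifts the centroid toward the residue
  expect_equal(localCenter(pair, 1, radius = 5, includeSelf = TRUE),
               c(3, 2, 3))
})

test_that("classification follows the distance and orientation rule", {
  # no environment: outside
  lone <- toyStructure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_false(classifyInside(lone, 1, radius = 5))
  # center 2 A away (< radius): inside regardless of side chain
  near <- toyStructure(rbind(c(0, 0, 0), c(2, 0, 0)),
                       cb = rbind(c(-1.53, 0, 0), c(3.53, 0, 0)))
  expect_true(classifyInside(near, 1, radius = 5))
  # center exactly at the radius: the strict distance test fails and the
  # orientation term decides (hand evaluation of the rule on these
  # coordinates: (ca - cb) . (ca - c) = -1.53 * 5 < 0 for cb away from c)
  away <- toyStructure(rbind(c(0, 0, 0), c(5, 0, 0)),
                       cb = rbind(c(-1.53, 0, 0), c(6.53, 0, 0)))
  expect_true(classifyInside(away, 1, radius = 5, orientationSign = 1))
  expect_false(classifyInside(away, 1, radius = 5, orientationSign = -1))
  toward <- toyStructure(rbind(c(0, 0, 0), c(5, 0, 0)),
                         cb = rbind(c(1.53, 0, 0), c(3.47, 0, 0)))
  expect_false(classifyInside(toward, 1, radius = 5, orientationSign = 1))
  expect_true(classifyInside(toward, 1, radius = 5, orientationSign = -1))
  # no C-beta: the distance disjunct alone decides
  noCb <- toyStructure(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_false(classifyInside(noCb, 1, radius = 5))
})

test_that("classification is invariant under rigid-body transformation", {
  s <- makeGlobule(40, seed = 9, cbOrientation = "out")
  st <- rigidTransform(s, seed = 21)
  for (i in c(1, 7, 19, 40)) {
    for (sgn in c(1, -1)) {
      expect_identical(classifyInside(s, i, orientationSign = sgn),
                       classifyInside(st, i, orientationSign = sgn))
    }
  }
})

test_that("counts accumulate per amino acid and are additive", {
  comp <- setNames(rep(0, 20), aminoAcids()); comp["A"] <- 1
  s <- makeGlobule(10, seed = 2, composition = comp)
  c1 <- accumulateCounts(list(s), radius = 5)
  df <- countsTable(c1)
  # compact globule: every residue has a close neighbor, all inside
  expect_equal(df$n_in[df$aa == "A"], 10L)
  expect_equal(df$n_out[df$aa == "A"], 0L)
  expect_equal(sum(df$n_in) + sum(df$n_out), 10L)

  s2 <- makeGlobule(15, seed = 3)
  cA <- accumulateCounts(list(s), radius = 5)
  cB <- accumulateCounts(list(s2), radius = 5)
  cAB <- accumulateCounts(list(s, s2), radius = 5)
  expect_equal(countsTable(cAB)$n_in,
               countsTable(cA)$n_in + countsTable(cB)$n_in)
  expect_equal(countsTable(cAB)$n_out,
               countsTable(cA)$n_out + countsTable(cB)$n_out)
  # order invariance
  cBA <- accumulateCounts(list(s2, s), radius = 5)
  expect_equal(countsTable(cAB), countsTable(cBA))
})

test_that("vectorized classification agrees with the per-residue rule", {
  s <- makeBuriedPairs(12, buriedProb = 0.5, seed = 5)
  fast <- eprofiler:::.classifyAll(s, radius = 5, orientationSign = -1,
                                   includeSelf = FALSE)
  slow <- vapply(seq_len(length(s)), function(i)
    classifyInside(s, i, radius = 5, orientationSign = -1), logical(1))
  expect_identical(fast, slow)
})

test_that("pseudoenergies follow the inverse-Boltzmann formula", {
  mk <- function(nin, nout, baseline = 100L) {
    df <- data.frame(aa = aminoAcids(), n_in = baseline, n_out = baseline,
                     stringsAsFactors = FALSE)
    df$n_in[df$aa == "A"] <- nin
    df$n_out[df$aa == "A"] <- nout
    new("BuriednessCounts", counts = df, sourceSet = "toy", radius = 5,
        orientationSign = 1)
  }
  getA <- function(tab) energyTable(tab)$e_star[energyTable(tab)$aa == "A"]
  expect_equal(getA(pseudoEnergies(mk(100L, 100L), pseudocount = 0)), 0)
  expect_equal(getA(pseudoEnergies(mk(200L, 100L), pseudocount = 0)), -log(2))
  expect_equal(getA(pseudoEnergies(mk(0L, 100L), pseudocount = 1)),
               -log(1 / 101))
  expect_error(pseudoEnergies(mk(0L, 0L, baseline = 0L), pseudocount = 0),
               "undefined")
  # sign convention: buried-biased < 0, exposed-biased > 0
  expect_lt(getA(pseudoEnergies(mk(500L, 50L), pseudocount = 1)), 0)
  expect_gt(getA(pseudoEnergies(mk(50L, 500L), pseudocount = 1)), 0)
})

test_that("pseudoenergy recovery converges to the generating log-odds", {
  # amino acid placed inside with probability p: recovered e* -> -ln(p/(1-p))
  comp <- setNames(rep(0, 20), aminoAcids()); comp["L"] <- 1
  for (p in c(0.3, 0.7)) {
    structs <- lapply(1:10, function(k)
      makeBuriedPairs(100, buriedProb = p, seed = 100 * p + k,
                      composition = comp))
    counts <- accumulateCounts(structs, radius = 5, orientationSign = -1)
    tab <- energyTable(pseudoEnergies(counts, pseudocount = 1))
    est <- tab$e_star[tab$aa == "L"]
    # 2000 classified residues: SE of the log-odds is about 0.05
    expect_equal(est, -log(p / (1 - p)), tolerance = 0.2)
  }
})

test_that("stats tables round-trip through TSV", {
  tab <- defaultEnergyTable()
  f <- tempfile(fileext = ".tsv")
  writeStats(tab, f)
  back <- readStats(f)
  expect_equal(energyTable(back), energyTable(tab))
  expect_equal(back@provenance$radius, tab@provenance$radius)
  expect_equal(back@provenance$pseudocount, tab@provenance$pseudocount)
  # extra comment lines are ignored
  writeLines(c("# extra\tcomment", readLines(f)), f)
  expect_equal(energyTable(readStats(f)), energyTable(tab))
  # a truncated table (19 rows) is rejected
  lines <- readLines(f)
  writeLines(lines[-length(lines)], f)
  expect_error(readStats(f), "20 canonical")
})

test_that("the bundled table is the documented seeded computation", {
  bundled <- defaultEnergyTable()
  regen <- syntheticEnergyTable()
  expect_equal(energyTable(regen), energyTable(bundled), tolerance = 1e-9)
  expect_match(bundled@provenance$source_set, "synthetic")
})
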