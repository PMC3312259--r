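# Distance matrices, UPGMA guide trees, progressive alignment, consensus,
# conservation and the text report.

makeProfileSet <- function(seeds, n = 24, tab = defaultEnergyTable()) {
  lapply(seq_along(seeds), function(k)
    computeProfile(makeHelix(n, seed = seeds[k]), tab,
                   id = paste0("p", letters[k])))
}

test_that("identical profiles give an all-zero distance matrix", {
  tab <- defaultEnergyTable()
  base <- computeProfile(makeHelix(20, seed = 1), tab)
  ps <- lapply(1:3, function(k) { q <- base; q@id <- paste0("c", k); q })
  D <- distanceMatrix(ps, nPerm = 30, seed = 2)
  expect_equal(unname(D), matrix(0, 3, 3))
  expect_identical(D, t(D))
})

test_that("distance matrices are symmetric with zero diagonal", {
  ps <- makeProfileSet(1:4)
  D <- distanceMatrix(ps, nPerm = 30, seed = 5)
  expect_identical(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_true(all(D >= 0))
})

test_that("UPGMA reproduces the hand-agglomerated example", {
  D <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(D)
  # first merge A with B at distance 2 (node height 1), then with C at
  # distance 8 (node height 4)
  expect_equal(treeMergeSets(tr), list(c("A", "B"), c("A", "B", "C")))
  expect_equal(tr@height, c(2, 8))
  expect_equal(tr@height / 2, c(1, 4))
})

test_that("UPGMA ties are broken lexicographically", {
  n <- 4
  D <- matrix(1, n, n); diag(D) <- 0
  labs <- c("d", "b", "c", "a")
  dimnames(D) <- list(labs, labs)
  tr <- upgmaTree(D)
  sets <- treeMergeSets(tr)
  # cluster label = smallest member, so {a,b} (labelled "a") absorbs "c"
  # before "c" and "d" can pair up
  expect_equal(sets[[1]], c("a", "b"))
  expect_equal(sets[[2]], c("a", "b", "c"))
  expect_equal(sets[[3]], c("a", "b", "c", "d"))
  expect_equal(treeMergeSets(tr), bruteUpgma(D)$merges)
})

test_that("UPGMA matches the brute-force reference on random matrices", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0.1, 10)
    M <- M + t(M)
    labs <- paste0("L", seq_len(n))
    dimnames(M) <- list(labs, labs)
    tr <- upgmaTree(M)
    ref <- bruteUpgma(M)
    expect_equal(treeMergeSets(tr), ref$merges)
    expect_equal(tr@height, ref$heights)
    expect_true(all(diff(tr@height) >= -1e-12))
  }
})

test_that("UPGMA heights agree with hclust average linkage", {
  set.seed(15)
  n <- 6
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- runif(15, 0.5, 5)
  M <- M + t(M)
  labs <- paste0("x", 1:n)
  dimnames(M) <- list(labs, labs)
  tr <- upgmaTree(M)
  hc <- hclust(as.dist(M), method = "average")
  expect_equal(sort(tr@height), sort(hc$height), tolerance = 1e-12)
})

test_that("guide trees export to parseable ultrametric Newick", {
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(D)
  f <- tempfile(fileext = ".nwk")
  writeGuideTree(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(ph)[1:3]
  expect_equal(unname(depths), rep(max(tr@height) / 2, 3), tolerance = 1e-9)
})

test_that("MEPAL of identical profiles is gap-free and fully conserved", {
  tab <- defaultEnergyTable()
  base <- computeProfile(makeHelix(24, seed = 3), tab)
  ps <- lapply(1:3, function(k) { q <- base; q@id <- paste0("c", k); q })
  res <- mepal(ps, nPerm = 25, seed = 4)
  msa <- res$msa
  expect_equal(length(msa), 24L)                      # no gap columns
  expect_false(anyNA(alignmentEnergies(msa)))
  expect_equal(conservation(msa), rep(1, 24))
  expect_equal(consensusEnergies(msa), energies(base))
  em <- alignmentEnergies(msa)
  for (r in 1:3) expect_equal(unname(em[r, ]), energies(base))
})

test_that("a two-profile progressive alignment equals the pairwise DP", {
  tab <- defaultEnergyTable()
  A <- computeProfile(makeHelix(20, seed = 5), tab, id = "A")
  B <- computeProfile(makeHelix(23, seed = 6), tab, id = "B")
  b <- buildBinner(c(energies(A), energies(B)), 20)
  pw <- globalAlign(A, B, b)
  D <- distanceMatrix(list(A, B), nPerm = 20, seed = 1)
  msa <- progressiveAlign(list(A, B), upgmaTree(D), binner = b)
  pr <- alignedPairs(pw)
  em <- alignmentEnergies(msa)
  expect_equal(ncol(em), nrow(pr))
  eA <- ifelse(is.na(pr[, "a"]), NA_real_, energies(A)[pr[, "a"]])
  eB <- ifelse(is.na(pr[, "b"]), NA_real_, energies(B)[pr[, "b"]])
  expect_equal(unname(em["A", ]), eA)
  expect_equal(unname(em["B", ]), eB)
  expect_gte(ncol(em), max(length(A), length(B)))
})

test_that("per-profile entry order is preserved in the alignment", {
  ps <- makeProfileSet(7:10, n = 18)
  res <- mepal(ps, nPerm = 20, seed = 9)
  em <- alignmentEnergies(res$msa)
  for (p in ps) {
    row <- em[p@id, ]
    expect_equal(unname(row[!is.na(row)]), energies(p))
  }
  expect_gte(ncol(em), 18L)
})

test_that("consensus picks the member with maximal summed similarity", {
  b <- buildBinner(seq(0, 21, length.out = 200), nBins = 20)
  # bin centers: construct energies in bins 3, 3, 9
  mids <- (c(b@boundaries[2] + b@boundaries[3],
             b@boundaries[8] + b@boundaries[9])) / 2
  col <- c(mids[1], mids[1] + 1e-4, mids[2])
  cons <- consensusEnergy(col, b)
  expect_equal(binOf(b, cons), 3L)        # the bin-3 members win
  expect_equal(cons, mids[1])             # tie inside bin 3: lower energy
  expect_equal(consensusEnergy(c(NA, 0.7, NA), b), 0.7)
  expect_equal(consensusEnergy(rep(5, 4), b), 5)
  expect_error(consensusEnergy(c(NA_real_, NA_real_), b), "all-gap")
})

test_that("conservation is the normalized pairwise score sum", {
  b <- buildBinner(rnorm(100), nBins = 20)
  expect_equal(conservationOf(rep(0.3, 5), b), 1)
  # maximum bin distance: (20 - 19) / 20
  expect_equal(conservationOf(c(-1e5, 1e5), b), 0.05)
  expect_equal(conservationOf(c(0.1, NA, NA), b), 1)        # convention
  expect_true(is.na(conservationOf(c(0.1, NA), b, singleValue = NA)))
  set.seed(16)
  for (rep in 1:20) {
    col <- rnorm(sample(2:6, 1))
    v <- conservationOf(col, b)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("the text report renders all three blocks deterministically", {
  tab <- defaultEnergyTable()
  base <- computeProfile(makeHelix(70, seed = 11), tab)
  ps <- lapply(1:2, function(k) { q <- base; q@id <- paste0("c", k); q })
  res <- mepal(ps, nPerm = 20, seed = 12)
  rep1 <- renderMepal(res$msa)
  rep2 <- renderMepal(res$msa)
  expect_identical(rep1, rep2)
  consRows <- grep("^conserv\\.", rep1, value = TRUE)
  glyphs <- gsub("^conserv\\.\\s+", "", consRows)
  expect_true(all(strsplit(paste(glyphs, collapse = ""), "")[[1]] == "9"))
  # report parses back to the column count (wrapped over segments)
  idRows <- grep("^c1 ", rep1, value = TRUE)
  total <- sum(nchar(gsub("^c1\\s+", "", idRows)))
  expect_equal(total, length(res$msa))
})

test_that("gap positions are rendered as dashes", {
  tab <- defaultEnergyTable()
  A <- computeProfile(makeHelix(12, seed = 13), tab, id = "A")
  B <- computeProfile(makeHelix(20, seed = 14), tab, id = "B")
  res <- mepal(list(A, B), nPerm = 20, seed = 15)
  if (any(is.na(alignmentEnergies(res$msa)))) {
    rows <- grep("^A ", renderMepal(res$msa), value = TRUE)
    expect_true(any(grepl("-", rows, fixed = TRUE)))
  }
  expect_gte(length(res$msa), 20L)
})
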