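test_that("Prevosti distances match closed forms and the summation oracle", {
  one <- function(a, b) {
    gm <- genotypeMatrix(matrix(c(a, b), 1, 2,
                                dimnames = list(NULL, c("x", "y"))),
                         S4Vectors::DataFrame(seqid = "s", pos = 1L,
                                              ref = "A", alt = "C"))
    prevostiDist(gm)["x", "y"]
  }
  expect_equal(one(0L, 2L), 1.0)    # AA vs aa
  expect_equal(one(0L, 1L), 0.5)    # AA vs Aa
  expect_equal(one(1L, 1L), 0.0)    # identical clones
  set.seed(55)
  gm <- randomGm(50, 20, codes = 0:3)
  got <- prevostiDist(gm)
  want <- prevostiOracle(genotypes(gm))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("Prevosti satisfies the metric axioms", {
  set.seed(56)
  for (trial in 1:5) {
    d <- prevostiDist(randomGm(30, 8, codes = 0:3))
    expect_true(all(diag(d) == 0))
    expect_identical(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("missing genotypes are rejected and filtered as specified", {
  gm <- randomGm(10, 4)
  expect_identical(genotypes(filterNoMissing(gm)), genotypes(gm))
  g <- genotypes(gm)
  g[3, 2] <- NA; g[7, 1] <- NA
  gm2 <- genotypeMatrix(g, gm@sites)
  expect_error(prevostiDist(gm2), "missing")
  expect_equal(nSites(filterNoMissing(gm2)), 8)
  # monomorphic sites are retained: no MAF floor
  mono <- genotypeMatrix(matrix(0L, 3, 4,
                                dimnames = list(NULL, letters[1:4])),
                         S4Vectors::DataFrame(seqid = "s", pos = 1:3,
                                              ref = "A", alt = "C"))
  expect_equal(nSites(filterNoMissing(mono)), 3)
})

test_that("MAF spectrum bins behave as defined", {
  allHet <- genotypeMatrix(matrix(1L, 4, 16,
                                  dimnames = list(NULL, sprintf("c%02d", 1:16))),
                           S4Vectors::DataFrame(seqid = "s", pos = 1:4,
                                                ref = "A", alt = "C"))
  sp <- mafSpectrum(allHet)
  expect_equal(sp$fraction[sp$bin == "(0.4,0.5]"], 1)
  expect_equal(sum(sp$fraction), 1)
  oneHet <- genotypeMatrix(
    matrix(c(1L, rep(0L, 15)), 1, 16,
           dimnames = list(NULL, sprintf("c%02d", 1:16))),
    S4Vectors::DataFrame(seqid = "s", pos = 1L, ref = "A", alt = "C"))
  expect_equal(siteInfo(oneHet)$maf, 1 / 32)
  expect_equal(mafSpectrum(oneHet)$fraction[1], 1)  # lowest bin
})

test_that("UPGMA reproduces the closed-form three-taxon tree", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(d)
  expect_true(ape::is.ultrametric(tr))
  # A and B are sisters at height 1
  ab <- ape::getMRCA(tr, c("A", "B"))
  depths <- ape::node.depth.edgelength(tr)
  height <- max(depths) - depths[ab]
  expect_equal(unname(height), 1)
  expect_error(upgmaTree(matrix(c(0, 1, 2, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("UPGMA agrees with a naive agglomeration oracle", {
  set.seed(57)
  for (trial in 1:10) {
    n <- sample(4:6, 1)
    gm <- randomGm(40, n, codes = 0:2)
    d <- prevostiDist(gm)
    tr <- upgmaTree(d)
    coph <- as.matrix(ape::cophenetic.phylo(tr))
    want <- upgmaOracle(d)
    ids <- rownames(d)
    expect_equal(coph[ids, ids], want[ids, ids], tolerance = 1e-9,
                 info = paste("trial", trial))
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  }
})

test_that("UPGMA recovers the generating topology from its distances", {
  set.seed(58)
  ok <- 0
  for (trial in 1:20) {
    tr <- ape::rcoal(8)
    d <- as.matrix(ape::cophenetic.phylo(tr))
    back <- upgmaTree(d)
    if (ape::dist.topo(ape::unroot(tr), ape::unroot(back)) == 0) ok <- ok + 1
  }
  expect_equal(ok, 20)
})

test_that("bootstrap support is 100% for a perfect two-group split", {
  set.seed(59)
  g <- rbind(matrix(rep(c(0L, 0L, 0L, 2L, 2L, 2L), 30), 30, 6, byrow = TRUE),
             matrix(sample(0:1, 60, replace = TRUE), 10, 6))
  colnames(g) <- sprintf("c%02d", 1:6)
  gm <- genotypeMatrix(g, S4Vectors::DataFrame(
    seqid = "s", pos = seq_len(nrow(g)), ref = "A", alt = "C"))
  tr <- bootstrapSupport(gm, nReps = 100, seed = 3)
  split <- ape::getMRCA(tr, c("c04", "c05", "c06"))
  lab <- tr$node.label[split - ape::Ntip(tr)]
  expect_equal(as.numeric(lab), 100)
  # seeded determinism
  tr2 <- bootstrapSupport(gm, nReps = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  # supports invariant under locus permutation
  set.seed(60)
  perm <- sample(nrow(g))
  gmP <- genotypeMatrix(g[perm, ], gm@sites[perm, ])
  trP <- bootstrapSupport(gmP, nReps = 100, seed = 3)
  expect_identical(tr$node.label, trP$node.label)
  # single replicate: supports are 0 or 100
  tr1 <- bootstrapSupport(gm, nReps = 1, seed = 4)
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 100)))
})

test_that("dosage PCA separates structured groups and sums variance to 100", {
  set.seed(61)
  g <- cbind(matrix(2L, 40, 3), matrix(0L, 40, 3)) # two pools
  noise <- matrix(sample(0:1, 40 * 6, replace = TRUE, prob = c(0.9, 0.1)),
                  40, 6)
  g <- pmin(g + noise, 2L)
  colnames(g) <- sprintf("c%02d", 1:6)
  gm <- genotypeMatrix(g, S4Vectors::DataFrame(
    seqid = "s", pos = 1:40, ref = "A", alt = "C"))
  p <- pcaGenotypes(gm)
  expect_equal(sum(p$percentVar), 100)
  pc1 <- p$coords[, 1]
  expect_true(all(sign(pc1[1:3]) == sign(pc1[1])))
  expect_true(all(sign(pc1[4:6]) == -sign(pc1[1])))
  # identical clones land on identical coordinates
  g2 <- g; g2[, 2] <- g2[, 1]
  gm2 <- genotypeMatrix(g2, gm@sites)
  p2 <- pcaGenotypes(gm2)
  expect_equal(p2$coords[1, ], p2$coords[2, ], tolerance = 1e-10)
  expect_error(pcaGenotypes(genotypeMatrix(
    matrix(1L, 5, 3, dimnames = list(NULL, c("a", "b", "c"))),
    S4Vectors::DataFrame(seqid = "s", pos = 1:5, ref = "A", alt = "C"))),
    "zero variance")
})
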