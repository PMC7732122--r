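# build a clonePileup from explicit reads placed on a reference
pileupFixture <- function(refSeq, reads, pos, status = NULL, quals = NULL) {
  n <- length(reads)
  if (is.null(status)) status <- rep("intact", n)
  if (is.null(quals)) quals <- strrep(rawToChar(as.raw(40 + 33)), nchar(reads))
  m1 <- data.frame(read = sprintf("r%03d", seq_len(n)), ref = 1L, pos = pos,
                   strand = "+", frac = 1, identity = 1,
                   specific = TRUE, accepted = TRUE)
  mapRes <- list(m1 = m1,
                 m2 = data.frame(read = character(0), ref = integer(0),
                                 pos = integer(0), strand = character(0),
                                 frac = numeric(0), identity = numeric(0),
                                 specific = logical(0), accepted = logical(0)),
                 pairStatus = status)
  pair <- list(r1 = mkReads(reads, quals), r2 = mkReads(character(0)))
  refs <- Biostrings::DNAStringSet(c(ref1 = refSeq))
  clonePileup(mapRes, pair, refs)
}

test_that("caller A honours depth, count and frequency filters", {
  set.seed(45)
  ref <- randomDna(60)
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 30, 30))[1]
  mkRead <- function(withAlt) {
    s <- substr(ref, 11, 50)
    if (withAlt) substr(s, 20, 20) <- alt
    s
  }
  callAt <- function(nRef, nAlt, status = NULL) {
    reads <- c(replicate(nRef, mkRead(FALSE)), replicate(nAlt, mkRead(TRUE)))
    pu <- pileupFixture(ref, reads, rep(11L, nRef + nAlt), status = status)
    callClone(pu)
  }
  expect_equal(nrow(callAt(2, 2)$callsA), 0)        # depth 4 < 5
  expect_equal(nrow(callAt(40, 20)$callsA), 0)      # depth 60 > 50
  het <- callAt(6, 4)$callsA                         # 40% alt at depth 10
  expect_equal(nrow(het), 1)
  expect_equal(het$pos, 30)
  expect_setequal(c(het$a1, het$a2), c(substr(ref, 30, 30), alt))
  expect_equal(nrow(callAt(9, 1)$callsA), 0)        # alt count 1 < 2
  expect_equal(nrow(callAt(7, 3)$callsA), 0)        # 30% < 40%
  hom <- callAt(1, 9)$callsA                        # ref share 10%: hom-alt
  expect_equal(c(hom$a1, hom$a2), c(alt, alt))
  # broken pairs are excluded from the caller-A pileup
  expect_equal(nrow(callAt(6, 4, status = rep("broken", 10))$callsA), 0)
})

test_that("caller B is the maximum-likelihood diploid genotype", {
  set.seed(46)
  ref <- randomDna(60)
  refBase <- substr(ref, 30, 30)
  alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  mkRead <- function(withAlt) {
    s <- substr(ref, 11, 50)
    if (withAlt) substr(s, 20, 20) <- alt
    s
  }
  homAlt <- callClone(pileupFixture(ref, replicate(20, mkRead(TRUE)),
                                    rep(11L, 20)))$callsB
  expect_equal(c(homAlt$a1, homAlt$a2), c(alt, alt))
  hetB <- callClone(pileupFixture(ref, c(replicate(10, mkRead(FALSE)),
                                         replicate(10, mkRead(TRUE))),
                                  rep(11L, 20)))$callsB
  expect_setequal(c(hetB$a1, hetB$a2), c(refBase, alt))
})

test_that("genotype likelihoods equal brute-force enumeration", {
  set.seed(47)
  for (i in 1:500) {
    d <- sample(5:50, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    bases <- sample(c(ref, alt), d, replace = TRUE,
                    prob = c(runif(1), runif(1)))
    quals <- sample(25:41, d, replace = TRUE)
    got <- genotypeLikelihood(bases, quals, ref, alt)$genotype
    want <- genotypeOracle(bases, quals, ref, alt)
    expect_identical(sort(got), want, info = paste("case", i))
  }
})

test_that("the C++ pileup likelihood sums match the R-side computation", {
  set.seed(48)
  ref <- randomDna(40)
  reads <- vapply(1:8, function(i) {
    s <- substr(ref, 1, 40)
    substr(s, 15, 15) <- sample(c("A", "C", "G", "T"), 1)
    s
  }, character(1))
  quals <- vapply(1:8, function(i)
    rawToChar(as.raw(sample(30:41, 40, replace = TRUE) + 33L)), character(1))
  pu <- pileupFixture(ref, reads, rep(1L, 8), quals = quals)
  st <- pu$stacks[[1]]
  bases <- substr(reads, 15, 15)
  qv <- vapply(quals, function(q) utf8ToInt(q)[15] - 33L, integer(1),
               USE.NAMES = FALSE)
  for (b in 1:4) {
    sel <- bases == c("A", "C", "G", "T")[b]
    e <- 10^(-qv[sel] / 10)
    expect_equal(st$homMatch[b, 15], sum(log(1 - e)), tolerance = 1e-12)
    expect_equal(st$mismatch[b, 15], sum(log(e / 3)), tolerance = 1e-12)
    expect_equal(st$hetMatch[b, 15],
                 sum(log(0.5 * (1 - e) + 0.5 * e / 3)), tolerance = 1e-12)
  }
})

test_that("concordance requires identical position, ref and genotype", {
  a <- data.frame(seqid = c("s", "s", "s"), pos = c(10L, 20L, 30L),
                  ref = "A", a1 = c("A", "C", "C"), a2 = "C",
                  depth = 10L, adRef = 5L, adAlt = 5L)
  b <- data.frame(seqid = c("s", "s"), pos = c(10L, 20L),
                  ref = "A", a1 = c("A", "C"), a2 = "C",
                  depth = 12L, adRef = 6L, adAlt = 6L)
  conc <- concordantCalls(a, b)
  expect_equal(conc$pos, c(10L, 20L))       # pos 30 in A only: dropped
  b2 <- b; b2$a1[1] <- "C"                  # A het vs B hom-alt at pos 10
  expect_equal(concordantCalls(a, b2)$pos, 20L)
  # concordant set is a subset of both callers
  expect_true(all(paste(conc$seqid, conc$pos) %in% paste(a$seqid, a$pos)))
  expect_true(all(paste(conc$seqid, conc$pos) %in% paste(b$seqid, b$pos)))
})

test_that("matrix building distinguishes hom-ref from missing by depth", {
  set.seed(49)
  ref <- randomDna(80)
  refBase <- substr(ref, 30, 30)
  alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  mkRead <- function(withAlt) {
    s <- substr(ref, 11, 50)
    if (withAlt) substr(s, 20, 20) <- alt
    s
  }
  # clone A: het call; clone B: callable hom-ref; clone C: depth 3 (missing)
  puA <- pileupFixture(ref, c(replicate(6, mkRead(FALSE)),
                              replicate(6, mkRead(TRUE))), rep(11L, 12))
  puB <- pileupFixture(ref, replicate(10, mkRead(FALSE)), rep(11L, 10))
  puC <- pileupFixture(ref, replicate(3, mkRead(FALSE)), rep(11L, 3))
  calls <- lapply(list(A = puA, B = puB, C = puC), function(p) {
    cl <- callClone(p)
    concordantCalls(cl$callsA, cl$callsB)
  })
  bm <- buildGenotypeMatrix(calls, list(A = puA, B = puB, C = puC))
  g <- genotypes(bm$gm)
  expect_equal(dim(g), c(1L, 3L))
  expect_equal(unname(g[1, ]), c(1L, 0L, NA))
  # the no-missing filter then drops the site
  expect_equal(nSites(filterNoMissing(bm$gm)), 0)
})

test_that("private alleles match an exhaustive per-site scan", {
  allIdentical <- genotypeMatrix(
    matrix(1L, 5, 3, dimnames = list(NULL, c("a", "b", "c"))),
    S4Vectors::DataFrame(seqid = "s", pos = 1:5, ref = "A", alt = "C"))
  expect_true(all(privateAlleles(allIdentical)$nPrivate == 0))
  oneHom <- genotypeMatrix(
    matrix(c(2L, 0L, 0L), 1, 3, dimnames = list(NULL, c("a", "b", "c"))),
    S4Vectors::DataFrame(seqid = "s", pos = 1L, ref = "A", alt = "C"))
  pa <- privateAlleles(oneHom)
  expect_equal(pa$nPrivate[pa$clone == "a"], 1)
  expect_equal(pa$nPrivateHom[pa$clone == "a"], 1)
  set.seed(50)
  gm <- randomGm(40, 5)
  pa <- privateAlleles(gm)
  g <- genotypes(gm)
  carrier <- function(code) g %in% code & !is.na(g)
  for (ci in seq_len(ncol(g))) {
    want <- 0L
    for (i in seq_len(nrow(g))) {
      for (al in list(c(0L, 1L), c(1L, 2L, 3L))) {
        has <- g[i, ] %in% al
        if (sum(has) == 1 && has[ci]) want <- want + 1L
      }
    }
    expect_equal(pa$nPrivate[ci], want, info = paste("clone", ci))
  }
})

test_that("never-covered references are flagged as candidate contaminants", {
  refs <- Biostrings::DNAStringSet(c(a = randomDna(300), b = randomDna(300)))
  mp <- list(m1 = data.frame(ref = c(1L, 1L), accepted = c(TRUE, TRUE)),
             m2 = data.frame(ref = c(1L, 2L), accepted = c(TRUE, FALSE)))
  expect_equal(flagUnmappedRefs(list(mp), refs), "b")
  mpEmpty <- list(m1 = data.frame(ref = integer(0), accepted = logical(0)),
                  m2 = data.frame(ref = integer(0), accepted = logical(0)))
  expect_warning(got <- flagUnmappedRefs(list(mpEmpty), refs), "no mapped")
  expect_setequal(got, c("a", "b"))
})

test_that("decoy references draw no clone reads and are flagged", {
  cfg <- simConfig(nGenes = 10, nDecoys = 2, seed = 51, dnaDepth = 15,
                   errorRate = 0.001, qJitter = 0, nRate = 0)
  g <- generateGenome(cfg)
  p <- generateClonePanel(g, cfg, 2)
  dna <- simulateDnaReads(p, cfg)
  refs <- scaffolds(g)   # includes the decoy scaffolds
  maps <- lapply(dna, function(d) mapClone(d, refs))
  flagged <- flagUnmappedRefs(maps, refs)
  decoyIds <- grep("decoy", names(refs), value = TRUE)
  expect_true(all(decoyIds %in% flagged))
  expect_equal(sort(flagged), sort(decoyIds))
})

test_that("the genotype VCF round-trips exactly", {
  set.seed(52)
  gm <- randomGm(25, 4, codes = c(0:3, NA))
  tf <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(gm, tf)
  back <- readGenotypeVcf(tf)
  expect_identical(genotypes(back), genotypes(gm))
  expect_identical(back@sites$pos, as.integer(gm@sites$pos))
  # independent reader agrees on the genotype codes
  v <- vcfR::read.vcfR(tf, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  codeOf <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "1/2" = 3L)
  want <- matrix(codeOf[gt], nrow(gt), ncol(gt))
  expect_equal(unname(genotypes(gm)), unname(want))
})
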