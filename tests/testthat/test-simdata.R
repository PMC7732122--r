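test_that("gene architectures follow the configured laws", {
  cfg <- simConfig(nGenes = 10, seed = 4)
  set.seed(99)
  arch <- sampleGeneArchitecture(cfg, 10000)
  counts <- lengths(arch$exonLens)
  expect_true(all(counts >= 1 & counts <= 24))
  expect_true(all(lengths(arch$intronLens) == counts - 1))
  # law means computed exactly from the truncated/clamped distributions
  kk <- 0:23
  pk <- dnbinom(kk, size = cfg@exonCountSize, mu = cfg@exonCountMu)
  pk[24] <- pk[24] + (1 - pnbinom(23, size = cfg@exonCountSize,
                                  mu = cfg@exonCountMu))
  lawCountMean <- sum((kk + 1) * pk)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - lawCountMean), 3 * se)
  expect_equal(median(counts), 2)
  exLens <- unlist(arch$exonLens)
  v <- 1:50000
  pv <- plnorm(v + 0.5, cfg@exonMeanLog, cfg@exonSdLog) -
    plnorm(v - 0.5, cfg@exonMeanLog, cfg@exonSdLog)
  lawLenMean <- sum(pmax(v, cfg@minExonLen) * pv) +
    cfg@minExonLen * plnorm(0.5, cfg@exonMeanLog, cfg@exonSdLog)
  # padding short transcripts up to 200 bp shifts the raw law slightly
  seL <- sd(exLens) / sqrt(length(exLens))
  expect_lt(abs(mean(exLens) - lawLenMean), 3 * seL + 5)
  inLens <- unlist(arch$intronLens)
  pv2 <- plnorm(v + 0.5, cfg@intronMeanLog, cfg@intronSdLog) -
    plnorm(v - 0.5, cfg@intronMeanLog, cfg@intronSdLog)
  lawInMean <- sum(pmax(v, cfg@minIntronLen) * pv2) +
    cfg@minIntronLen * plnorm(0.5, cfg@intronMeanLog, cfg@intronSdLog)
  seI <- sd(inLens) / sqrt(length(inLens))
  expect_lt(abs(mean(inLens) - lawInMean), 3 * seI)
})

test_that("degenerate exon-count law yields intronless genes", {
  cfg <- simConfig(nGenes = 20, seed = 2, exonCountMu = 0)
  g <- generateGenome(cfg)
  perGene <- table(S4Vectors::mcols(geneModels(g))$gene_id)
  expect_true(all(perGene == 1))
})

test_that("genome generation is seed-deterministic and internally consistent", {
  cfg <- simConfig(nGenes = 8, nDecoys = 1, seed = 42)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(scaffolds(g1)), as.character(scaffolds(g2)))
  expect_identical(as.character(proteins(g1)), as.character(proteins(g2)))
  # exon models spell the transcripts
  for (gid in head(names(transcripts(g1)), 4)) {
    spliced <- orphangene:::spliceTranscript(scaffolds(g1), geneModels(g1), gid)
    expect_identical(spliced, as.character(transcripts(g1)[[gid]]))
  }
  # planted CDS is the longest ORF of its transcript
  for (gid in head(names(transcripts(g1)), 3)) {
    orf <- predictOrf(as.character(transcripts(g1)[[gid]]), minAa = 30)
    expect_identical(orf$protein,
                     as.character(proteins(g1)[[gid]]))
  }
})

test_that("clone panel density, genotypes and truth consistency", {
  cfg <- simConfig(nGenes = 40, seed = 5)
  g <- generateGenome(cfg)
  p <- generateClonePanel(g, cfg, 4)
  L <- sum(Biostrings::width(p@scaffolds))
  nS <- nrow(truthVariants(p))
  se <- sqrt(L * cfg@snpRate * (1 - cfg@snpRate))
  expect_lt(abs(nS - L * cfg@snpRate), 3 * se)
  codes <- p@hap1 + p@hap2
  expect_true(all(codes %in% 0:2))
  # rebuilding haplotypes reproduces ref/alt alleles at truth sites
  haps <- cloneHaplotypes(p, "clone02")
  tr <- truthVariants(p)
  idx <- sample(nrow(tr), min(50, nrow(tr)))
  for (i in idx) {
    b <- as.character(Biostrings::subseq(haps$hap1[[tr$seqid[i]]],
                                         tr$pos[i], tr$pos[i]))
    expect_identical(b, unname(ifelse(p@hap1[i, "clone02"],
                                      tr$alt[i], tr$ref[i])))
  }
  expect_error(generateClonePanel(g, cfg, 1), "at least 2")
})

test_that("zero SNP rate gives clones identical to the founder", {
  cfg <- simConfig(nGenes = 3, seed = 6, snpRate = 1e-9)
  g <- generateGenome(cfg)
  p <- generateClonePanel(g, cfg, 2)
  expect_equal(nrow(truthVariants(p)), 0)
  haps <- cloneHaplotypes(p, "clone01")
  expect_identical(as.character(haps$hap1), as.character(p@scaffolds))
  tf <- tempfile(fileext = ".vcf")
  writeTruthVcf(p, tf)
  expect_false(any(!startsWith(readLines(tf), "#")))
})

test_that("RNA reads are spliced, stranded, 150 bp and error-free when asked", {
  cfg <- simConfig(nGenes = 5, seed = 9, errorRate = 0, nRate = 0,
                   rnaDepth = 10)
  g <- generateGenome(cfg)
  p <- generateClonePanel(g, cfg, 2)
  rna <- simulateRnaReads(p, g, cfg)
  expect_true(all(Biostrings::width(rna$r1) == 150))
  expect_true(all(Biostrings::width(rna$r2) == 150))
  expect_true(all(grepl("proto=R2-sense", names(rna$r2))))
  haps <- cloneHaplotypes(p, referenceClone(p))
  txs <- unlist(lapply(names(transcripts(g)), function(gid) {
    if (!paste0("scf_", gid) %in% names(p@scaffolds))
      return(as.character(transcripts(g)[[gid]]))
    c(orphangene:::spliceTranscript(haps$hap1, geneModels(g), gid),
      orphangene:::spliceTranscript(haps$hap2, geneModels(g), gid))
  }))
  big <- paste(txs, collapse = "NN")
  idx <- sample(length(rna$r2), 40)
  for (i in idx) {
    s <- as.character(rna$r2[[i]])   # read 2 carries the sense strand
    expect_true(grepl(s, big, fixed = TRUE))
  }
  for (i in head(idx, 10)) {
    s <- as.character(Biostrings::reverseComplement(rna$r1[[i]]))
    expect_true(grepl(s, big, fixed = TRUE))
  }
  # same seed twice: byte-identical
  rna2 <- simulateRnaReads(p, g, cfg)
  expect_identical(as.character(rna$r1), as.character(rna2$r1))
})

test_that("DNA read counts track configured depth and haplotype balance", {
  cfg <- simConfig(nGenes = 20, seed = 10, dnaDepth = 20, errorRate = 0,
                   nRate = 0)
  g <- generateGenome(cfg)
  p <- generateClonePanel(g, cfg, 3)
  dna <- simulateDnaReads(p, cfg, clones = "clone02")
  L <- sum(Biostrings::width(p@scaffolds))
  expected <- 20 * L / 300
  n <- length(dna$clone02$r1)
  expect_lt(abs(n - expected), 4 * sqrt(expected) + 0.02 * expected)
  hap <- as.integer(sub(".*hap=", "", names(dna$clone02$r1)))
  expect_lt(abs(mean(hap == 1) - 0.5), 4 * sqrt(0.25 / n))
  # per-clone streams do not depend on the requested subset
  dnaAll <- simulateDnaReads(p, cfg)
  expect_identical(as.character(dna$clone02$r1),
                   as.character(dnaAll$clone02$r1))
})

test_that("fastq round-trip preserves reads and qualities", {
  cfg <- simConfig(nGenes = 2, seed = 3, rnaDepth = 5)
  g <- generateGenome(cfg)
  p <- generateClonePanel(g, cfg, 2)
  rna <- simulateRnaReads(p, g, cfg)
  pre <- tempfile()
  writeFastqPair(rna, pre)
  back <- readFastqPair(paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
  expect_identical(as.character(back$r1), as.character(rna$r1))
  expect_identical(as.character(Biostrings::quality(back$r2)),
                   as.character(Biostrings::quality(rna$r2)))
})
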