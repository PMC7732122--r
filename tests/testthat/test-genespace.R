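test_that("mapping accepts by length fraction and similarity", {
  set.seed(25)
  ref <- Biostrings::DNAStringSet(c(r1 = randomDna(1000)))
  exact <- substr(as.character(ref[[1]]), 201, 350)
  mut <- exact
  for (at in c(10, 40, 70, 100, 120, 140))   # 6 mismatches: 96% identity
    substr(mut, at, at) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, at, at))[1]
  pair <- asPair(c(exact, mut), c(exact, mut))
  mp95 <- mapReads(pair, ref, 1.0, 0.95)
  expect_true(all(mp95$m1$accepted))
  expect_equal(mp95$m1$identity[1], 1.0)
  expect_true(mp95$m1$specific[1])
  expect_equal(mp95$m1$pos[1], 201)
  mp98 <- mapReads(pair, ref, 1.0, 0.98)
  expect_true(mp98$m1$accepted[1])
  expect_false(mp98$m1$accepted[2])   # 96% identity fails at 0.98
})

test_that("reads occurring identically in two references are non-specific", {
  set.seed(26)
  shared <- randomDna(400)
  refs <- Biostrings::DNAStringSet(c(
    a = paste0(randomDna(200), shared, randomDna(200)),
    b = paste0(randomDna(150), shared, randomDna(250))))
  rd <- substr(shared, 100, 249)
  mp <- mapReads(asPair(rd, rd), refs, 1.0, 0.95)
  expect_false(mp$m1$specific[1])
  expect_false(mp$m1$accepted[1])
})

test_that("recruitment extracts intact and broken pairs, both mates", {
  set.seed(27)
  ref <- Biostrings::DNAStringSet(c(r = randomDna(2000)))
  s <- as.character(ref[[1]])
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  intact1 <- substr(s, 101, 250);  intact2 <- rc(substr(s, 251, 400))
  broken1 <- substr(s, 501, 650);  broken2 <- randomDna(150)
  un1 <- randomDna(150);           un2 <- randomDna(150)
  pair <- asPair(c(intact1, broken1, un1), c(intact2, broken2, un2))
  mp <- mapReads(pair, ref, 1.0, 0.95, insertMean = 300, insertSd = 50)
  expect_equal(mp$pairStatus, c("intact", "broken", "unmapped"))
  rec <- extractRecruited(mp, pair)
  expect_equal(length(rec$r1), 2)   # both mates of intact AND broken pairs
  expect_equal(as.character(rec$r2[[2]]), broken2)  # the unmapped mate too
})

test_that("guided assembly keeps guides when nothing is recruited", {
  guides <- Biostrings::DNAStringSet(c(g1 = randomDna(500)))
  expect_warning(
    out <- guidedAssemble(list(r1 = character(0), r2 = character(0)), guides),
    "no recruited reads")
  expect_equal(as.character(out)[[1]], as.character(guides)[[1]])
  # quoted ladder defaults
  f <- formals(guidedAssemble)
  expect_equal(eval(f$kmin), 25L)
  expect_equal(eval(f$kmax), 100L)
  expect_equal(eval(f$kstep), 5L)
})

test_that("guided assembly reconstructs a covered region from reads alone", {
  set.seed(28)
  region <- randomDna(1200)
  rd <- chopPairs(region, 120)
  out <- guidedAssemble(list(r1 = rd$r1, r2 = rd$r2), NULL)
  expect_equal(length(out), 1)
  got <- as.character(out[[1]])
  expect_true(grepl(got, region, fixed = TRUE) ||
                grepl(as.character(Biostrings::reverseComplement(out[[1]])),
                      region, fixed = TRUE))
  expect_gte(Biostrings::width(out)[1], 1100)
})

test_that("iteration recovers a full 3-exon gene within 8 rounds", {
  set.seed(29)
  exons <- replicate(3, randomDna(400))
  introns <- replicate(2, randomDna(250))
  geneSeq <- paste0(exons[1], introns[1], exons[2], introns[2], exons[3])
  scaffold <- paste0(randomDna(300), geneSeq, randomDna(300))
  unigene <- Biostrings::DNAStringSet(c(UG0001 = paste(exons, collapse = "")))
  rd <- chopPairs(scaffold, round(25 * nchar(scaffold) / 300))
  pair <- asPair(rd$r1, rd$r2)
  states <- iterateGenespace(unigene, pair, maxIter = 8)
  expect_lte(length(states), 8)
  rebuilt <- vapply(states, `[[`, integer(1), "rebuiltCount")
  expect_true(all(diff(rebuilt) >= 0))
  expect_equal(rebuilt[length(rebuilt)], 1)
  fin <- states[[length(states)]]$contigs
  hasGene <- any(vapply(as.character(fin), function(s)
    grepl(geneSeq, s, fixed = TRUE) ||
      grepl(geneSeq, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), fixed = TRUE), logical(1)))
  expect_true(hasGene)
  # recruited read sets grow monotonically on error-free data
  recr <- vapply(states, `[[`, integer(1), "recruitedReads")
  expect_true(all(diff(recr) >= 0))
})

test_that("iteration stops immediately when no read matches the Unigene", {
  set.seed(30)
  unigene <- Biostrings::DNAStringSet(c(UG0001 = randomDna(600)))
  rd <- chopPairs(randomDna(2000), 60)
  states <- suppressWarnings(iterateGenespace(unigene, asPair(rd$r1, rd$r2)))
  expect_equal(length(states), 1)
  expect_equal(states[[1]]$rebuiltCount, 0)
})

test_that("genespace composition applies the longest-form rule", {
  set.seed(31)
  u1 <- randomDna(600)                       # rebuilt longer (DNA form)
  u2 <- randomDna(500)                       # no DNA hit: carried over
  u3 <- randomDna(400); u4 <- randomDna(450) # both inside one DNA contig
  uni <- Biostrings::DNAStringSet(c(UG1 = u1, UG2 = u2, UG3 = u3, UG4 = u4))
  contigs <- Biostrings::DNAStringSet(c(
    c1 = paste0(randomDna(100), u1, randomDna(200)),
    c2 = paste0(u3, randomDna(150), u4),
    c3 = substr(u1, 1, 300)))   # shorter partial match, must lose to c1
  comp <- composeGenespace(uni, contigs)
  rep <- comp$report
  expect_equal(rep$class[rep$unigene_id == "UG1"], "longer")
  expect_equal(rep$class[rep$unigene_id == "UG2"], "unmatched")
  expect_setequal(rep$class[rep$unigene_id %in% c("UG3", "UG4")],
                  "concatenated")
  mc <- S4Vectors::mcols(comp$genespace)
  expect_equal(sum(mc$origin == "dna_contig"), 2)
  # one record carries both members
  expect_true(any(mc$members == "UG3,UG4"))
  # carried-over sequence is verbatim
  rna <- which(mc$origin == "rna_contig")
  expect_equal(as.character(comp$genespace[[rna]]), u2)
  # every Genespace record aligns to >= 1 member or is a carry-over
  expect_true(all(nchar(mc$members) > 0))
})

test_that("collinear chains beat exhaustive subset enumeration", {
  set.seed(32)
  for (trial in 1:20) {
    n <- sample(4:9, 1)
    h <- data.frame(
      qstart = sample(1:500, n), sstart = sample(1:500, n))
    len <- sample(30:80, n, replace = TRUE)
    h$qend <- h$qstart + len; h$send <- h$sstart + len
    h$score <- len * 2
    got <- orphangene:::chainHsps(h, maxOverlap = 0L)
    gotScore <- sum(h$score[got])
    best <- 0
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      idx <- idx[order(h$qstart[idx])]
      ok <- TRUE
      if (length(idx) > 1) {
        for (j in 2:length(idx)) {
          a <- idx[j - 1]; b <- idx[j]
          if (!(h$qstart[b] > h$qstart[a] && h$qend[b] > h$qend[a] &&
                h$qstart[b] > h$qend[a] &&
                h$sstart[b] > h$sstart[a] && h$send[b] > h$send[a] &&
                h$sstart[b] > h$send[a])) { ok <- FALSE; break }
        }
      }
      if (ok) best <- max(best, sum(h$score[idx]))
    }
    expect_equal(gotScore, best, info = paste("trial", trial))
  }
})
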