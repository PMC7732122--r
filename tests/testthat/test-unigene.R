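# local affine-gap Smith-Waterman oracle (BLOSUM62, open 11 extend 1),
# written directly from the recurrences
swOracle <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1); X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - 12, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 12, Y[i, j - 1] - 1)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + B[a[i - 1], b[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

randomProtein <- function(n) paste(sample(
  c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T",
    "W","Y","V"), n, replace = TRUE), collapse = "")

# deterministic reverse translation (one codon per residue)
backTranslate <- function(p) {
  tab <- Biostrings::GENETIC_CODE
  aa <- strsplit(p, "")[[1]]
  paste(vapply(aa, function(x) names(tab)[tab == x][1], character(1)),
        collapse = "")
}

test_that("an exact back-translation gives a perfect best hit", {
  set.seed(15)
  p <- randomProtein(150)
  contig <- paste0(randomDna(30), backTranslate(p), randomDna(30))
  prot <- Biostrings::AAStringSet(c(P1 = p))
  hits <- translatedSearch(Biostrings::DNAStringSet(c(c1 = contig)), prot)
  expect_gte(nrow(hits), 1)
  best <- hits[which.min(hits$evalue), ]
  expect_equal(best$protein, "P1")
  expect_equal(best$identityPct, 100)
  expect_equal(best$coveragePct, 100)
  expect_lt(best$evalue, 1e-20)
})

test_that("random contigs have no hit at the 1e-20 cutoff", {
  set.seed(16)
  prot <- Biostrings::AAStringSet(c(P1 = randomProtein(200)))
  hits <- translatedSearch(
    Biostrings::DNAStringSet(c(c1 = randomDna(600))), prot)
  expect_equal(nrow(hits), 0)
})

test_that("alignment scores agree with a Smith-Waterman oracle", {
  set.seed(17)
  p <- randomProtein(80)
  # mutate ~20% of residues for a mid-identity case
  q <- strsplit(p, "")[[1]]
  at <- sample(80, 16)
  q[at] <- sample(c("A","G","S","T","V","L"), 16, replace = TRUE)
  q <- paste(q, collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(p), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  expect_equal(Biostrings::score(pa), swOracle(q, p))
})

test_that("the Unigene selection rules act exactly as specified", {
  # fixture: 6 contigs vs 3 proteins exercising every rule
  mkc <- function(lens) {
    x <- Biostrings::DNAStringSet(vapply(lens, randomDna, character(1)))
    names(x) <- sprintf("c%02d", seq_along(x)); x
  }
  set.seed(18)
  ctgA <- mkc(c(1000, 800, 500, 600))   # assembly one
  ctgB <- mkc(c(1000, 700))             # assembly two
  hitsA <- data.frame(
    contig = c("c01", "c02", "c03", "c04"),
    protein = c("P1", "P1", "P2", "P3"),
    frame = 1L,
    identityPct = c(90, 95, 80, 90),
    coveragePct = c(95, 95, 65, 92),    # c03 fails the 70% coverage rule
    score = 500, bitScore = 200, evalue = 1e-50)
  hitsB <- data.frame(
    contig = c("c01", "c02"),
    protein = c("P1", "P3"),
    frame = 1L,
    identityPct = c(95, 90),            # same length as A's P1 winner: higher
    coveragePct = c(95, 92),            # identity wins across assemblies
    score = 500, bitScore = 200, evalue = 1e-50)
  uni <- buildUnigene(list(A = hitsA, B = hitsB),
                      list(A = ctgA, B = ctgB))
  expect_equal(length(uni), 2)          # P2's only contig was excluded
  mc <- S4Vectors::mcols(uni)
  p1 <- which(mc$bbhProtein == "P1")
  # within A, the longest contig (c01, 1000bp) beat c02 (800); across
  # assemblies lengths tie at 1000 and B's higher identity wins
  expect_equal(mc$sourceAssembly[p1], "B")
  expect_equal(mc$identityPct[p1], 95)
  p3 <- which(mc$bbhProtein == "P3")
  # across assemblies the longest form wins: B's 700 bp beats A's 600 bp
  expect_equal(mc$sourceAssembly[p3], "B")
  expect_equal(mc$sourceContig[p3], "c02")
  # bbh ids unique (non-redundancy)
  expect_false(any(duplicated(mc$bbhProtein)))
})

test_that("longest contig wins within an assembly, identity breaks ties", {
  set.seed(19)
  ctg <- Biostrings::DNAStringSet(
    c(a = randomDna(1000), b = randomDna(800)))
  hits <- data.frame(contig = c("a", "b"), protein = "P", frame = 1L,
                     identityPct = c(80, 99), coveragePct = c(90, 90),
                     score = 1, bitScore = 100, evalue = 1e-40)
  uni <- buildUnigene(list(X = hits), list(X = ctg))
  expect_equal(S4Vectors::mcols(uni)$sourceContig, "a")  # longest wins
  ctg2 <- Biostrings::DNAStringSet(
    c(a = randomDna(900), b = randomDna(900)))
  uni2 <- buildUnigene(list(X = hits), list(X = ctg2))
  expect_equal(S4Vectors::mcols(uni2)$sourceContig, "b") # tie: identity 99
})

test_that("contaminant purge behaves on edge cases", {
  set.seed(20)
  uni <- Biostrings::DNAStringSet(c(UG0001 = randomDna(400),
                                    UG0002 = randomDna(400)))
  expect_identical(as.character(suppressMessages(
    purgeContaminants(uni, character(0)))), as.character(uni))
  expect_warning(suppressMessages(purgeContaminants(uni, names(uni))),
                 "all Unigene records")
  expect_warning(suppressMessages(purgeContaminants(uni, "nope")),
                 "unknown ids")
})
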