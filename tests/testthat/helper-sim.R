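# shared fixture builders: all synthetic, generated at test time

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# molecule-wise chopping of a sequence into paired 150 bp reads with random
# physical mate order; mirrors how fragment libraries cover molecule ends
chopPairs <- function(mol, nFrag, insertMean = 300, insertSd = 75,
                      readLen = 150) {
  st <- integer(0); en <- integer(0)
  L <- nchar(mol)
  while (length(st) < nFrag) {
    pos <- 1L
    while (pos <= L - readLen + 1L) {
      fl <- max(readLen, as.integer(round(rnorm(1, insertMean, insertSd))))
      e <- min(pos + fl - 1L, L)
      if (e - pos + 1L >= readLen) { st <- c(st, pos); en <- c(en, e) }
      pos <- e + 1L
    }
  }
  fwd <- substring(mol, st, st + readLen - 1L)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(mol, en - readLen + 1L, en))))
  sw <- runif(length(st)) < 0.5
  list(r1 = ifelse(sw, rev, fwd), r2 = ifelse(sw, fwd, rev))
}

# wrap bare sequences (all quality Q40) into a QualityScaledDNAStringSet pair
asPair <- function(r1, r2, q = 40L) {
  qc <- rawToChar(as.raw(q + 33L))
  mk <- function(s) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(s),
      Biostrings::PhredQuality(vapply(nchar(s), function(L)
        strrep(qc, L), character(1))))
    names(x) <- sprintf("rd%05d", seq_along(s))
    x
  }
  list(r1 = mk(r1), r2 = mk(r2))
}

mkReads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- if (is.null(ids)) sprintf("r%05d", seq_along(seqs)) else ids
  x
}

# brute-force maximal-scoring-substring oracle for the quality trim:
# maximises sum(limit - perr) over substrings; ties by smallest start, then
# smallest end; perr = 1 for non-ACGT bases
mottOracle <- function(seq, qual, limit) {
  L <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  perr <- 10^(-(utf8ToInt(qual) - 33) / 10)
  perr[!b %in% c("A", "C", "G", "T")] <- 1
  sc <- limit - perr
  S <- c(0, cumsum(sc))
  # A[j, i] = score of substring [i, j]; evaluate every one of them
  A <- outer(S[-1], S[-(L + 1)], "-")
  A[upper.tri(A)] <- -Inf
  best <- max(A)
  if (best <= 1e-15) return(list(range = c(0L, 0L), score = 0))
  cand <- which(A > best - 1e-12, arr.ind = TRUE)   # ties
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  list(range = c(cand[1, 2], cand[1, 1]), score = best)
}

# exact score of a substring under the trim objective
mottScore <- function(seq, qual, limit, from, to) {
  if (from < 1 || to < from) return(0)
  b <- strsplit(seq, "")[[1]][from:to]
  perr <- 10^(-(utf8ToInt(qual)[from:to] - 33) / 10)
  perr[!b %in% c("A", "C", "G", "T")] <- 1
  sum(limit - perr)
}

# brute-force six-frame longest-ORF oracle
orfOracle <- function(seq, minAa = 100L) {
  best <- 0L
  for (fr in 1:3) {
    for (s in list(seq, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))))) {
      n <- nchar(s) - fr + 1L
      n <- n - n %% 3L
      if (n < 6) next
      cod <- substring(s, seq(fr, fr + n - 3L, 3L), seq(fr + 2L, fr + n - 1L, 3L))
      aa <- ifelse(cod == "ATG", "M",
                   ifelse(cod %in% c("TAA", "TAG", "TGA"), "*", "x"))
      open <- NA
      for (i in seq_along(aa)) {
        if (is.na(open) && aa[i] == "M") open <- i
        if (!is.na(open) && aa[i] == "*") {
          if (i - open > best) best <- i - open
          open <- NA
        }
      }
    }
  }
  if (best >= minAa) best else 0L
}

# direct per-read genotype-likelihood enumeration over the 3 biallelic
# diploid genotypes (the oracle for the likelihood caller)
genotypeOracle <- function(bases, quals, ref, alt) {
  gts <- list(c(ref, ref), c(ref, alt), c(alt, alt))
  ll <- vapply(gts, function(g) {
    sum(vapply(seq_along(bases), function(i) {
      e <- 10^(-quals[i] / 10)
      p <- mean(vapply(g, function(a)
        if (bases[i] == a) 1 - e else e / 3, numeric(1)))
      log(p)
    }, numeric(1)))
  }, numeric(1))
  sort(gts[[which.max(ll)]])
}

# brute-force Prevosti distance by explicit per-locus summation
prevostiOracle <- function(geno) {
  freq <- function(code) switch(as.character(code),
    "0" = c(1, 0, 0), "1" = c(0.5, 0.5, 0),
    "2" = c(0, 1, 0), "3" = c(0, 0.5, 0.5))
  n <- ncol(geno); m <- nrow(geno)
  d <- matrix(0, n, n, dimnames = list(colnames(geno), colnames(geno)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- 0
    for (l in seq_len(m))
      tot <- tot + sum(abs(freq(geno[l, i]) - freq(geno[l, j])))
    d[i, j] <- tot / (2 * m)
  }
  d
}

# naive O(n^3) average-linkage agglomeration returning merge heights per
# leaf pair (cophenetic matrix); independent of hclust
upgmaOracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dd <- d
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      if (dd[active[a], active[b]] < bd - 1e-15) {
        bd <- dd[active[a], active[b]]; best <- c(a, b)
      }
    }
    ia <- active[best[1]]; ib <- active[best[2]]
    for (x in clusters[[ia]]) for (y in clusters[[ib]])
      coph[x, y] <- coph[y, x] <- bd
    na <- length(clusters[[ia]]); nb <- length(clusters[[ib]])
    for (other in setdiff(active, c(ia, ib)))
      dd[ia, other] <- dd[other, ia] <-
        (na * dd[ia, other] + nb * dd[ib, other]) / (na + nb)
    clusters[[ia]] <- c(clusters[[ia]], clusters[[ib]])
    active <- setdiff(active, ib)
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# random GenotypeMatrix with optional missingness
randomGm <- function(nSites, nClones, pMiss = 0, codes = 0:2) {
  g <- matrix(sample(codes, nSites * nClones, replace = TRUE),
              nSites, nClones,
              dimnames = list(NULL, sprintf("cl%02d", seq_len(nClones))))
  if (pMiss > 0) g[runif(length(g)) < pMiss] <- NA
  genotypeMatrix(g, S4Vectors::DataFrame(
    seqid = rep("s1", nSites), pos = seq_len(nSites),
    ref = rep("A", nSites), alt = rep("C", nSites)))
}
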