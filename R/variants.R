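#' Map a clone's genomic reads to the Genespace
#'
#' Stringent mode uses length fraction 0.95 with 90\% identity; relaxed mode
#' (for a divergent taxon, the lavandin analogue) 0.90 with 80\% identity.
#' Non-specific reads are excluded by [mapReads()] itself.
#'
#' @param pair clone read pair list.
#' @param genespace `DNAStringSet` reference.
#' @param stringent logical.
#' @param ... passed to [mapReads()].
#' @return a [mapReads()] result.
#' @export
mapClone <- function(pair, genespace, stringent = TRUE, ...) {
  if (stringent) mapReads(pair, genespace, 0.95, 0.90, ...)
  else mapReads(pair, genespace, 0.90, 0.80, ...)
}

#' Build quality-filtered pileups for one clone
#'
#' Only accepted, specific placements contribute. The caller-A view uses
#' reads from intact pairs whose base AND 5-base flanking window qualities
#' reach `minqA` (default 25); the caller-B view uses intact and broken
#' pairs with base quality >= `minqB` (default 30) and accumulates the
#' per-base genotype-likelihood terms.
#'
#' @param mapRes a [mapClone()] result.
#' @param pair the mapped reads.
#' @param refs the reference `DNAStringSet`.
#' @param minqA,flank,minqB quality filters.
#' @return list of class `clonePileup`: per-reference stacks plus `refNames`
#'   and `refSeqs`.
#' @export
clonePileup <- function(mapRes, pair, refs, minqA = 25L, flank = 5L,
                        minqB = 30L) {
  collect <- function(m, reads, mateStatus) {
    sel <- which(m$accepted)
    if (length(sel) == 0) {
      return(data.frame(ref = integer(0), pos = integer(0),
                        seq = character(0), qual = character(0),
                        useA = logical(0), useB = logical(0)))
    }
    s <- as.character(reads)[sel]
    q <- as.character(Biostrings::quality(reads))[sel]
    minus <- m$strand[sel] == "-"
    if (any(minus)) {
      s[minus] <- as.character(reverseComplement(DNAStringSet(s[minus])))
      q[minus] <- vapply(q[minus], function(x)
        paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
        USE.NAMES = FALSE)
    }
    data.frame(ref = m$ref[sel], pos = m$pos[sel], seq = s, qual = q,
               useA = mateStatus[sel] == "intact",
               useB = mateStatus[sel] %in% c("intact", "broken"))
  }
  p1 <- collect(mapRes$m1, pair$r1, mapRes$pairStatus)
  p2 <- collect(mapRes$m2, pair$r2, mapRes$pairStatus)
  p <- rbind(p1, p2)
  res <- pileup_cpp(width(refs), p$ref, p$pos, p$seq, p$qual,
                    p$useA, p$useB, as.integer(minqA), as.integer(flank),
                    as.integer(minqB))
  structure(list(stacks = res, refNames = names(refs),
                 refSeqs = as.character(refs)), class = "clonePileup")
}

BASES <- c("A", "C", "G", "T")

# maximum-likelihood diploid genotype from accumulated per-base terms.
# Returns list(genotype = c(a1, a2) sorted, logliks named RR/RA/AA).
mlGenotypeFromSums <- function(refBase, altBase, homMatch, mismatch, hetMatch) {
  r <- match(refBase, BASES); a <- match(altBase, BASES)
  others <- setdiff(1:4, c(r, a))
  llRR <- homMatch[r] + sum(mismatch[setdiff(1:4, r)])
  llAA <- homMatch[a] + sum(mismatch[setdiff(1:4, a)])
  llRA <- hetMatch[r] + hetMatch[a] + sum(mismatch[others])
  ll <- c(RR = llRR, RA = llRA, AA = llAA)
  g <- names(ll)[which.max(ll)]   # deterministic: RR > RA > AA on exact ties
  gt <- switch(g, RR = c(refBase, refBase), RA = sort(c(refBase, altBase)),
               AA = c(altBase, altBase))
  list(genotype = gt, logliks = ll)
}

#' Maximum-likelihood diploid genotype for a base/quality stack
#'
#' The likelihood of genotype g is the product over reads of P(base | g)
#' with per-base error e = 10^(-Q/10): 1 - e for a base matching a
#' homozygous allele, e/3 for a base absent from g, and (1-e)/2 + e/6 for a
#' base matching one allele of a heterozygote. This is the unit the
#' likelihood caller applies at every candidate site; exposed so it can be
#' checked against direct enumeration.
#'
#' @param bases character vector of read bases (A/C/G/T).
#' @param quals integer Phred qualities.
#' @param refBase,altBase the two candidate alleles.
#' @return list(genotype, logliks) as in the caller.
#' @export
genotypeLikelihood <- function(bases, quals, refBase, altBase) {
  homMatch <- mismatch <- hetMatch <- numeric(4)
  for (i in seq_along(bases)) {
    b <- match(bases[i], BASES)
    if (is.na(b)) next
    e <- 10^(-quals[i] / 10)
    homMatch[b] <- homMatch[b] + log(1 - e)
    mismatch[b] <- mismatch[b] + log(e / 3)
    hetMatch[b] <- hetMatch[b] + log(0.5 * (1 - e) + 0.5 * e / 3)
  }
  mlGenotypeFromSums(refBase, altBase, homMatch, mismatch, hetMatch)
}

#' Call variants in one clone with both callers
#'
#' Caller A (frequency caller): bases pass at quality >= 25 including the
#' 5-base flanks; a site is callable at filtered depth 5..50; an allele
#' passes with count >= 2 and frequency >= 40\% of the site coverage; two
#' passing alleles give the genotype (top two by count), a single passing
#' non-reference allele gives hom-alt. Caller B (likelihood caller): bases
#' pass at quality >= 30; the maximum-likelihood diploid genotype over
#' (ref, top alt) is reported, then the same depth/count/frequency filters
#' as caller A are applied. Hom-ref genotypes are non-calls for both.
#'
#' @param pileup a [clonePileup()].
#' @param minCov,maxCov depth window (5, 50).
#' @param minCount,minFreq alt-allele filters (2, 0.4).
#' @return list `callsA`, `callsB`: data.frames seqid, pos (1-based), ref,
#'   a1, a2 (sorted genotype), depth, adRef, adAlt.
#' @export
callClone <- function(pileup, minCov = 5L, maxCov = 50L, minCount = 2L,
                      minFreq = 0.4) {
  outA <- list(); outB <- list()
  for (r in seq_along(pileup$stacks)) {
    st <- pileup$stacks[[r]]
    refSeq <- pileup$refSeqs[r]
    L <- nchar(refSeq)
    if (L == 0) next
    refIdx <- match(strsplit(refSeq, "")[[1]], BASES)
    cA <- st$countsA; cB <- st$countsB
    okRef <- !is.na(refIdx)
    refCntA <- ifelse(okRef, cA[cbind(refIdx, seq_len(L))], 0L)
    refCntB <- ifelse(okRef, cB[cbind(refIdx, seq_len(L))], 0L)
    nonrefA <- st$depthA - refCntA
    nonrefB <- st$depthB - refCntB
    cand <- which(okRef & (nonrefA >= minCount | nonrefB >= minCount))
    for (p in cand) {
      ref <- BASES[refIdx[p]]
      # --- caller A ---
      dA <- st$depthA[p]
      if (dA >= minCov && dA <= maxCov) {
        cnt <- cA[, p]
        pass <- which(cnt >= minCount & cnt / dA >= minFreq)
        passNonref <- setdiff(pass, refIdx[p])
        if (length(passNonref) > 0) {
          ord <- pass[order(-cnt[pass], pass)]
          gt <- if (length(ord) >= 2) sort(BASES[ord[1:2]])
                else c(BASES[ord[1]], BASES[ord[1]])
          alt <- setdiff(gt, ref)[1]
          outA[[length(outA) + 1L]] <- data.frame(
            seqid = pileup$refNames[r], pos = p, ref = ref,
            a1 = gt[1], a2 = gt[2], depth = dA,
            adRef = cnt[refIdx[p]],
            adAlt = cnt[match(alt, BASES)])
        }
      }
      # --- caller B ---
      dB <- st$depthB[p]
      if (dB >= minCov && dB <= maxCov && nonrefB[p] >= minCount) {
        cntB <- cB[, p]
        nr <- setdiff(order(-cntB, seq_len(4)), refIdx[p])
        altIdx <- nr[1]
        if (cntB[altIdx] >= minCount &&
            nonrefB[p] / dB >= minFreq) {
          ml <- mlGenotypeFromSums(ref, BASES[altIdx],
                                   st$homMatch[, p], st$mismatch[, p],
                                   st$hetMatch[, p])
          gt <- ml$genotype
          if (!all(gt == ref)) {
            outB[[length(outB) + 1L]] <- data.frame(
              seqid = pileup$refNames[r], pos = p, ref = ref,
              a1 = gt[1], a2 = gt[2], depth = dB,
              adRef = cntB[refIdx[p]], adAlt = cntB[altIdx])
          }
        }
      }
    }
  }
  empty <- data.frame(seqid = character(0), pos = integer(0),
                      ref = character(0), a1 = character(0),
                      a2 = character(0), depth = integer(0),
                      adRef = integer(0), adAlt = integer(0))
  list(callsA = if (length(outA)) do.call(rbind, outA) else empty,
       callsB = if (length(outB)) do.call(rbind, outB) else empty)
}

#' Intersect the two callers
#'
#' A variant is kept only when both callers report the same position with
#' the same reference allele and the identical unordered genotype.
#'
#' @param callsA,callsB data.frames from [callClone()].
#' @return data.frame in the same shape (depth/AD taken from caller A).
#' @export
concordantCalls <- function(callsA, callsB) {
  keyA <- paste(callsA$seqid, callsA$pos)
  keyB <- paste(callsB$seqid, callsB$pos)
  i <- match(keyA, keyB)
  ok <- !is.na(i) & callsA$ref == callsB$ref[i] &
    callsA$a1 == callsB$a1[i] & callsA$a2 == callsB$a2[i]
  callsA[ok, , drop = FALSE]
}

#' Build the multi-clone genotype matrix
#'
#' Sites are the union of concordant variant positions over clones. A clone
#' without a call at a site is hom-ref when its caller-A-filtered depth lies
#' in the callable window (5..50) and missing otherwise — the rule that
#' later defines "no missing genotype data".
#'
#' @param concList named list (per clone) of [concordantCalls()] results.
#' @param pileups named list (per clone) of [clonePileup()] objects.
#' @param minCov,maxCov callable-depth window.
#' @return list: `gm` (a [GenotypeMatrix-class]), `dp` and `adAlt` integer
#'   matrices aligned with it.
#' @export
buildGenotypeMatrix <- function(concList, pileups, minCov = 5L, maxCov = 50L) {
  clones <- names(concList)
  stopifnot(length(clones) >= 2, !is.null(names(pileups)))
  allCalls <- do.call(rbind, lapply(clones, function(cl) {
    x <- concList[[cl]]
    if (nrow(x)) cbind(x, clone = cl) else NULL
  }))
  if (is.null(allCalls) || nrow(allCalls) == 0)
    stop("no concordant calls in any clone")
  key <- paste(allCalls$seqid, allCalls$pos)
  sites <- !duplicated(key)
  sk <- key[sites]
  seqid <- allCalls$seqid[sites]; pos <- allCalls$pos[sites]
  ref <- allCalls$ref[sites]
  o <- order(seqid, pos)
  sk <- sk[o]; seqid <- seqid[o]; pos <- pos[o]; ref <- ref[o]
  nS <- length(sk)
  # primary/secondary alt per site by total carriage
  alt1 <- character(nS); alt2 <- rep(NA_character_, nS)
  geno <- matrix(NA_integer_, nS, length(clones),
                 dimnames = list(NULL, clones))
  dp <- matrix(0L, nS, length(clones), dimnames = list(NULL, clones))
  ad <- matrix(0L, nS, length(clones), dimnames = list(NULL, clones))
  rows <- match(key, sk)
  for (i in seq_len(nS)) {
    sel <- which(rows == i)
    alleles <- c(allCalls$a1[sel], allCalls$a2[sel])
    alleles <- alleles[alleles != ref[i]]
    tab <- sort(table(alleles), decreasing = TRUE)
    alt1[i] <- names(tab)[1]
    if (length(tab) >= 2) alt2[i] <- names(tab)[2]
  }
  for (ci in seq_along(clones)) {
    cl <- clones[ci]
    x <- concList[[cl]]
    xi <- if (nrow(x)) match(paste(x$seqid, x$pos), sk) else integer(0)
    if (length(xi)) {
      for (j in seq_along(xi)) {
        i <- xi[j]
        if (is.na(i)) next
        g <- c(x$a1[j], x$a2[j])
        code <- if (all(g == ref[i])) 0L
          else if (setequal(g, c(ref[i], alt1[i]))) 1L
          else if (all(g == alt1[i])) 2L
          else 3L
        geno[i, ci] <- code
        dp[i, ci] <- x$depth[j]
        ad[i, ci] <- x$adAlt[j]
      }
    }
    # imputation at sites without a call: hom-ref iff callable depth
    pu <- pileups[[cl]]
    ridx <- match(seqid, pu$refNames)
    depthAt <- vapply(seq_len(nS), function(i) {
      if (is.na(ridx[i])) return(0L)
      d <- pu$stacks[[ridx[i]]]$depthA
      if (pos[i] >= 1 && pos[i] <= length(d)) d[pos[i]] else 0L
    }, integer(1))
    noCall <- is.na(geno[, ci])
    callable <- depthAt >= minCov & depthAt <= maxCov
    geno[noCall & callable, ci] <- 0L
    dp[noCall, ci] <- depthAt[noCall]
  }
  alt <- ifelse(is.na(alt2), alt1, paste(alt1, alt2, sep = ","))
  gm <- genotypeMatrix(geno, DataFrame(seqid = seqid, pos = pos,
                                       ref = ref, alt = alt))
  list(gm = gm, dp = dp, adAlt = ad)
}

#' Per-clone private alleles
#'
#' An allele is private to a clone when that clone carries it and no other
#' clone does; homozygous carriage is counted separately. All alleles at a
#' site (reference included) are examined.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return data.frame: clone, nPrivate, nPrivateHom.
#' @export
privateAlleles <- function(gm) {
  g <- genotypes(gm)
  clones <- colnames(g)
  tot <- integer(length(clones)); hom <- integer(length(clones))
  carriesRef <- g %in% c(0L, 1L) & !is.na(g);  dim(carriesRef) <- dim(g)
  carriesAlt1 <- g %in% c(1L, 2L, 3L) & !is.na(g); dim(carriesAlt1) <- dim(g)
  carriesAlt2 <- g == 3L & !is.na(g); dim(carriesAlt2) <- dim(g)
  count <- function(carry, homCode) {
    nCarry <- rowSums(carry, na.rm = TRUE)
    priv <- which(nCarry == 1L)
    for (i in priv) {
      ci <- which(carry[i, ])
      tot[ci] <<- tot[ci] + 1L
      if (!is.na(g[i, ci]) && g[i, ci] == homCode) hom[ci] <<- hom[ci] + 1L
    }
  }
  count(carriesRef, 0L)
  count(carriesAlt1, 2L)
  # a second alt (code 3) is het by construction: never counted homozygous
  count(carriesAlt2, -1L)
  data.frame(clone = clones, nPrivate = tot, nPrivateHom = hom)
}

#' Flag reference sequences never covered by any clone
#'
#' Genespace sequences onto which no read maps in any of the clone mapping
#' jobs are candidate contaminants and feed [purgeContaminants()].
#'
#' @param mapResList list of [mapClone()] results (one per clone).
#' @param refs the reference `DNAStringSet` that was mapped against.
#' @return character vector of flagged reference names.
#' @export
flagUnmappedRefs <- function(mapResList, refs) {
  n <- length(refs)
  counts <- integer(n)
  for (mp in mapResList) {
    hit <- c(mp$m1$ref[mp$m1$accepted], mp$m2$ref[mp$m2$accepted])
    if (length(hit)) {
      t <- tabulate(hit, nbins = n)
      counts <- counts + t
    }
  }
  if (sum(counts) == 0)
    warning("no mapped reads in any clone; flagging every reference")
  names(refs)[counts == 0L]
}

#' Heterozygous fraction of each clone's variant calls
#'
#' Computed among the clone's non-reference genotype calls (hom-ref is not a
#' call in a per-clone caller VCF): het / (het + hom-alt).
#'
#' @param gm a [GenotypeMatrix-class].
#' @return named numeric vector per clone.
#' @export
heterozygosityPerClone <- function(gm) {
  g <- genotypes(gm)
  apply(g, 2, function(x) {
    het <- sum(x %in% c(1L, 3L), na.rm = TRUE)
    hom <- sum(x == 2L, na.rm = TRUE)
    if (het + hom == 0) NA_real_ else het / (het + hom)
  })
}

#' Compare called genotypes with simulator truth
#'
#' Valid when the calling reference is the simulator's scaffold set (truth
#' coordinates). Site-level precision/recall over segregating truth sites
#' and per-genotype accuracy over clone x site calls.
#'
#' @param gm a [GenotypeMatrix-class] from [buildGenotypeMatrix()].
#' @param panel the [ClonePanel-class] truth.
#' @return list: precision, recall, genotypeAccuracy, nCalledSites,
#'   nTruthSites.
#' @export
evaluateCalls <- function(gm, panel) {
  truthCodes <- panel@hap1 + panel@hap2
  seg <- rowSums(truthCodes > 0) > 0
  truthKey <- paste(panel@truth$seqid, panel@truth$pos)[seg]
  si <- gm@sites
  callKey <- paste(si$seqid, si$pos)
  tp <- sum(callKey %in% truthKey)
  precision <- tp / length(callKey)
  recall <- tp / length(truthKey)
  idx <- match(callKey, paste(panel@truth$seqid, panel@truth$pos))
  ok <- 0L; tot <- 0L
  clones <- intersect(colnames(genotypes(gm)), panel@clones)
  for (cl in clones) {
    called <- genotypes(gm)[, cl]
    truth <- ifelse(is.na(idx), 0L, truthCodes[idx, cl])
    # zygosity accuracy of actual variant calls (hom-ref entries are
    # callable-depth imputations, not caller output)
    use <- !is.na(called) & called > 0L
    tot <- tot + sum(use)
    ok <- ok + sum(called[use] == truth[use])
  }
  list(precision = precision, recall = recall,
       genotypeAccuracy = ok / tot,
       nCalledSites = length(callKey), nTruthSites = length(truthKey))
}
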