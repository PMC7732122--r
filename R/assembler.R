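#' De novo de Bruijn assembly of paired reads
#'
#' Builds the graph from read-1 k-mers (canonicalized), prunes k-mers seen
#' fewer than `minCount` times and dead-end tips shorter than 2k, and
#' resolves bubbles using read-2 path support: a branch is supported when at
#' least one read-2 spells it (all its k-mers occur in the read-2 set). When
#' several branches are supported the higher mean k-mer coverage wins, ties
#' lexicographically; bubbles with no supported branch keep both branches as
#' separate contigs. Contigs are maximal non-branching paths of at least
#' `minLen` bp, reported in canonical orientation.
#'
#' @param r1,r2 read sets (`QualityScaledDNAStringSet`, `DNAStringSet` or
#'   character). `r2` defaults to `r1` when mate roles are not distinguished.
#' @param k odd k-mer size in `[15, 101]`.
#' @param minCount k-mer coverage cutoff (default 2).
#' @param minLen minimum contig length (default 200, the shortest contigs the
#'   downstream selection admits).
#' @param trusted optional sequences whose k-mers are exempt from coverage
#'   pruning (used by the guided assembly).
#' @return `DNAStringSet` of contigs named `c000001 ...` with a `coverage`
#'   metadata column (mean k-mer count).
#' @export
assembleReads <- function(r1, r2 = r1, k = 31L, minCount = 2L, minLen = 200L,
                          trusted = NULL) {
  if (!(k >= 15 && k <= 101)) stop("k must be in [15, 101]")
  s1 <- as.character(r1)
  s2 <- as.character(r2)
  tr <- if (is.null(trusted)) character(0) else as.character(trusted)
  if (!any(nchar(s1) >= k) && length(tr) == 0) {
    warning("no reads of length >= k; returning an empty assembly")
    return(DNAStringSet())
  }
  res <- dbg_assemble_cpp(s1, s2, as.integer(k), as.integer(minCount),
                          as.integer(minLen), tr)
  out <- DNAStringSet(res$seq)
  if (length(out))
    names(out) <- sprintf("c%06d", seq_along(out))
  S4Vectors::mcols(out)$coverage <- res$coverage
  out
}

#' Assembly summary metrics
#'
#' N50 is the length at which the cumulative descending-sorted contig length
#' first reaches half the total assembly length; GC is (G+C)/total.
#'
#' @param contigs `DNAStringSet` of contigs.
#' @param orfMinAa minimum ORF length (amino acids) for the ORF count.
#' @return one-row data.frame of metrics.
#' @export
assemblyMetrics <- function(contigs, orfMinAa = 100L) {
  if (length(contigs) == 0) stop("empty assembly")
  w <- sort(width(contigs), decreasing = TRUE)
  total <- sum(w)
  n50 <- w[which(cumsum(w) >= total / 2)[1]]
  comp <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE)
  gc <- 100 * sum(comp[, c("C", "G")]) / sum(comp[, c("A", "C", "G", "T")])
  orfs <- vapply(as.character(contigs),
                 function(s) {
                   o <- predictOrf(s, minAa = orfMinAa)
                   if (is.null(o)) 0L else o$length
                 }, integer(1), USE.NAMES = FALSE)
  data.frame(nContigs = length(contigs), totalLen = total,
             minLen = min(w), maxLen = max(w), meanLen = mean(w),
             n50 = n50, gcPercent = gc, nWithOrf = sum(orfs > 0))
}

#' Longest open reading frame over six frames
#'
#' Scans the three forward and three reverse-complement frames for the
#' longest ATG-to-stop ORF; an ORF is reported only when a stop codon closes
#' it and the encoded protein reaches `minAa` residues (start methionine
#' included, stop excluded).
#'
#' @param x character or `DNAString` contig sequence.
#' @param minAa minimum protein length in residues (default 100).
#' @return `NULL`, or list(length, frame, protein) with frame in
#'   `{1,2,3,-1,-2,-3}`.
#' @export
predictOrf <- function(x, minAa = 100L) {
  s <- toupper(as.character(x))
  best <- NULL
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    seq <- if (fr > 0) s else
      as.character(reverseComplement(DNAString(s)))
    off <- abs(fr) - 1L
    n <- nchar(seq) - off
    n <- n - (n %% 3L)
    if (n < 6) next
    aa <- suppressWarnings(as.character(
      translate(DNAString(substr(seq, off + 1L, off + n)),
                if.fuzzy.codon = "X")))
    m <- gregexpr("M[^*]*\\*", aa)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length") - 1L
    i <- which.max(lens)
    if (lens[i] >= minAa && (is.null(best) || lens[i] > best$length)) {
      best <- list(length = lens[i], frame = fr,
                   protein = substr(aa, m[i], m[i] + lens[i] - 1L))
    }
  }
  best
}

#' Map-back evaluation of an assembly
#'
#' Maps the assembly's own read pairs back to the contigs and reports the
#' read-mapping quality metrics: the fraction of pairs with both mates
#' mapped, the fraction of "good" pairs (both mates on the same contig, in
#' proper orientation, aligned over their full length), per-base coverage
#' gaps, and a support flag per contig (good-pair coverage of at least 1 over
#' at least 90\% of its bases).
#'
#' @param contigs `DNAStringSet`.
#' @param pair list with `r1`, `r2` read sets.
#' @param similarityFraction minimum identity of an accepted placement.
#' @return list: `metrics` (one-row data.frame: pctPairsMapped, pctGoodPairs,
#'   uncoveredBases, nContigsWithGap) and `supported` (named logical).
#' @export
evaluateAssembly <- function(contigs, pair, similarityFraction = 0.95) {
  nPairs <- length(pair$r1)
  if (nPairs == 0 || length(contigs) == 0) {
    return(list(metrics = data.frame(pctPairsMapped = 0, pctGoodPairs = 0,
                                     uncoveredBases = sum(width(contigs)),
                                     nContigsWithGap = length(contigs)),
                supported = setNames(logical(length(contigs)), names(contigs))))
  }
  mp <- mapReads(pair, contigs, lengthFraction = 1.0,
                 similarityFraction = similarityFraction)
  ok1 <- mp$m1$accepted; ok2 <- mp$m2$accepted
  mapped <- ok1 & ok2
  good <- mapped & mp$m1$ref == mp$m2$ref &
    mp$m1$strand != mp$m2$strand &
    mp$m1$frac >= 1 - 1e-9 & mp$m2$frac >= 1 - 1e-9 &
    ifelse(mp$m1$strand == "+",
           mp$m1$pos <= mp$m2$pos + width(pair$r2),
           mp$m2$pos <= mp$m1$pos + width(pair$r1))
  cov <- vector("list", length(contigs))
  for (i in seq_along(contigs)) cov[[i]] <- integer(width(contigs)[i])
  addCov <- function(df, rl, sel) {
    for (j in which(sel)) {
      ref <- df$ref[j]
      lo <- max(1L, df$pos[j])
      hi <- min(width(contigs)[ref], df$pos[j] + rl[j] - 1L)
      if (hi >= lo) cov[[ref]][lo:hi] <<- cov[[ref]][lo:hi] + 1L
    }
  }
  addCov(mp$m1, width(pair$r1), good)
  addCov(mp$m2, width(pair$r2), good)
  uncovered <- vapply(cov, function(x) sum(x == 0L), integer(1))
  supported <- vapply(cov, function(x) mean(x >= 1L) >= 0.9, logical(1))
  names(supported) <- names(contigs)
  list(metrics = data.frame(
         pctPairsMapped = 100 * mean(mapped),
         pctGoodPairs = 100 * mean(good),
         uncoveredBases = sum(uncovered),
         nContigsWithGap = sum(uncovered > 0)),
       supported = supported)
}
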