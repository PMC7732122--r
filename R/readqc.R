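#' Trimming configuration
#'
#' The quality trim keeps, per read, the maximal-scoring segment under the
#' per-base score `limit - p_err` (modified Mott algorithm); `limit = 0.001`
#' corresponds in practice to keeping segments of average quality above Q30.
#' Ambiguous bases score as errors of probability 1, so a kept segment never
#' contains an N. Adapters are clipped from the 3' end before quality
#' trimming; reads shorter than `minLen` after trimming are discarded.
#'
#' @param limit error-probability threshold in (0, 1).
#' @param minLen minimum retained read length, bp.
#' @param adapters character vector of adapter sequences (may be empty).
#' @param minOverlap minimum adapter overlap at the 3' end.
#' @param maxMismatchFrac mismatch budget of the adapter match.
#' @return list used by [trimReads()] and [trimPairs()].
#' @export
trimConfig <- function(limit = 0.001, minLen = 70L, adapters = character(0),
                       minOverlap = 5L, maxMismatchFrac = 0.1) {
  stopifnot(limit > 0, limit < 1, minLen >= 1)
  list(limit = limit, minLen = as.integer(minLen), adapters = adapters,
       minOverlap = as.integer(minOverlap), maxMismatchFrac = maxMismatchFrac)
}

#' Quality- and adapter-trim reads
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param cfg a [trimConfig()] list.
#' @return list: `reads` (trimmed survivors), `keep` (logical over input),
#'   `range` (matrix of 1-based retained start/end per input read, 0 when
#'   discarded), `basesIn`/`basesOut`.
#' @examples
#' r <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(a = paste(rep("ACGT", 30), collapse = ""))),
#'   Biostrings::PhredQuality(paste(rep("I", 120), collapse = "")))
#' trimReads(r, trimConfig())$keep
#' @export
trimReads <- function(reads, cfg = trimConfig()) {
  seqs <- as.character(reads)
  quals <- as.character(Biostrings::quality(reads))
  basesIn <- sum(nchar(seqs))
  if (length(cfg$adapters)) {
    cut <- adapter_trim_cpp(seqs, cfg$adapters, cfg$minOverlap,
                            cfg$maxMismatchFrac)
    seqs <- substring(seqs, 1L, cut)
    quals <- substring(quals, 1L, cut)
  }
  rng <- mott_trim_cpp(seqs, quals, cfg$limit)
  len <- ifelse(rng[, 1] > 0, rng[, 2] - rng[, 1] + 1L, 0L)
  keep <- len >= cfg$minLen
  rng[!keep, ] <- 0L
  out <- asFastq(substring(seqs[keep], rng[keep, 1], rng[keep, 2]),
                 substring(quals[keep], rng[keep, 1], rng[keep, 2]),
                 names(reads)[keep])
  list(reads = out, keep = keep, range = rng,
       basesIn = basesIn, basesOut = sum(len[keep]))
}

#' Trim a mate pair, keeping pair bookkeeping
#'
#' Pairs in which both mates survive stay paired; single survivors go to the
#' orphan set. Mates are matched on the first whitespace-delimited token of
#' the read name and must arrive record-synchronized.
#'
#' @param pair list with `r1`, `r2` (see [readFastqPair()]).
#' @param cfg a [trimConfig()] list.
#' @return list: `paired` (list `r1`,`r2`), `orphans`, and `report` (read and
#'   base counts plus the retained-base fraction).
#' @export
trimPairs <- function(pair, cfg = trimConfig()) {
  tok <- function(x) sub("\\s.*$", "", names(x))
  if (!identical(tok(pair$r1), tok(pair$r2)))
    stop("mate files are desynchronized: read ids differ")
  t1 <- trimReads(pair$r1, cfg)
  t2 <- trimReads(pair$r2, cfg)
  both <- t1$keep & t2$keep
  only1 <- t1$keep & !t2$keep
  only2 <- t2$keep & !t1$keep
  sel <- function(tr, mask) {
    idx <- which(tr$keep)
    tr$reads[match(which(mask), idx)]
  }
  orphans <- c(sel(t1, only1), sel(t2, only2))
  basesIn <- t1$basesIn + t2$basesIn
  basesOut <- t1$basesOut + t2$basesOut
  list(paired = list(r1 = sel(t1, both), r2 = sel(t2, both)),
       orphans = orphans,
       report = list(pairsIn = length(pair$r1), pairsKept = sum(both),
                     orphans = length(orphans),
                     basesIn = basesIn, basesOut = basesOut,
                     retainedBaseFraction = basesOut / basesIn))
}
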