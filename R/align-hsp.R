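#' @importFrom stats uniroot
NULL

# Karlin-Altschul lambda for an ungapped match/mismatch scheme at uniform
# base composition: solves sum p_ij exp(lambda * s_ij) = 1.
kaLambdaNuc <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 5))$root
}

# Expected number of chance HSPs at or above `score` in an m x n search space.
# K = 0.41 is the standard ungapped nucleotide constant; lambda is computed
# for the actual scoring scheme.
kaEvalue <- function(score, m, n, lambda, K = 0.41) {
  K * m * n * exp(-lambda * score)
}

#' Nucleotide HSP search
#'
#' Finds high-scoring segment pairs between a query and a set of subjects by
#' shared-k-mer diagonal runs (merged across gaps up to `maxGap`), scores them
#' with a +2/-3 scheme and attaches Karlin-Altschul e-values. Query
#' coordinates are reported in the oriented query (reverse complement for
#' minus-strand HSPs), 1-based closed; subject coordinates are always on the
#' forward subject.
#'
#' @param query character or `DNAString`(Set element) query sequence.
#' @param subjects `DNAStringSet` or character vector of subjects.
#' @param k seed length (default 13).
#' @param maxGap maximum spacing between seed starts merged into one HSP.
#' @param match,mismatch scoring scheme.
#' @return data.frame: subject, strand, qstart, qend, sstart, send, length,
#'   matches, identity, score, evalue.
#' @export
nucHsps <- function(query, subjects, k = 13L, maxGap = 40L,
                    match = 2, mismatch = -3) {
  q <- as.character(query)
  s <- as.character(subjects)
  h <- find_hsps_cpp(q, s, as.integer(k), as.integer(maxGap))
  if (nrow(h) == 0) {
    return(data.frame(subject = integer(0), strand = character(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      length = integer(0), matches = integer(0),
                      identity = numeric(0), score = numeric(0),
                      evalue = numeric(0)))
  }
  len <- h$qend - h$qstart
  score <- match * h$matches + mismatch * (len - h$matches)
  lambda <- kaLambdaNuc(match, mismatch)
  ev <- kaEvalue(score, nchar(q), nchar(s)[h$subject], lambda)
  data.frame(subject = h$subject, strand = h$strand,
             qstart = h$qstart + 1L, qend = h$qend,
             sstart = h$sstart + 1L, send = h$send,
             length = len, matches = h$matches,
             identity = h$matches / len, score = score, evalue = ev)
}

# Maximal-scoring collinear chain (both coordinates strictly increasing, one
# subject, one strand) by quadratic dynamic programming; HSP counts are small.
# Overlaps up to `maxOverlap` between neighbours are allowed and trimmed later.
chainHsps <- function(h, maxOverlap = 12L) {
  n <- nrow(h)
  if (n == 0) return(integer(0))
  o <- order(h$qstart, h$sstart)
  h <- h[o, , drop = FALSE]
  best <- h$score
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      qok <- h$qstart[j] > h$qstart[i] & h$qend[j] > h$qend[i] &
        h$qstart[j] > h$qend[i] - maxOverlap
      sok <- h$sstart[j] > h$sstart[i] & h$send[j] > h$send[i] &
        h$sstart[j] > h$send[i] - maxOverlap
      if (qok && sok && best[i] + h$score[j] > best[j]) {
        best[j] <- best[i] + h$score[j]
        prev[j] <- i
      }
    }
  }
  j <- which.max(best)
  chain <- integer(0)
  while (!is.na(j)) { chain <- c(j, chain); j <- prev[j] }
  o[chain]
}

# does any HSP of `query` against `subjects` reach the e-value cutoff?
hasNucHit <- function(query, subjects, evalueMax = 1e-6, k = 13L) {
  h <- nucHsps(query, subjects, k = k)
  any(h$evalue <= evalueMax)
}

# fraction of the query covered by the best single subject, using the
# maximal collinear HSP chain per (subject, strand)
bestChainCoverage <- function(query, subjects, evalueMax = 1e-6, k = 13L) {
  h <- nucHsps(query, subjects, k = k)
  h <- h[h$evalue <= evalueMax, , drop = FALSE]
  if (nrow(h) == 0) return(0)
  qlen <- nchar(as.character(query))
  best <- 0
  for (sb in unique(h$subject)) {
    for (st in unique(h$strand[h$subject == sb])) {
      hs <- h[h$subject == sb & h$strand == st, , drop = FALSE]
      ch <- chainHsps(hs)
      cov <- sum(hs$qend[ch] - hs$qstart[ch] + 1)
      cov <- min(cov, qlen) / qlen
      if (cov > best) best <- cov
    }
  }
  best
}
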