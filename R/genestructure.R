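#' Infer exon/intron architecture of a Genespace sequence
#'
#' Aligns the Unigene (spliced) form against its genomic Genespace form:
#' local HSPs at e-value <= `evalueMax` are chained by dynamic programming
#' into the maximal-scoring collinear chain (one strand, both coordinate
#' systems strictly increasing); overlapping neighbours are trimmed at the
#' midpoint of the overlap. Chained subject intervals are the exons; subject
#' gaps whose query-side gap is at most `qGapTol` bp are introns (larger
#' query gaps indicate unassembled transcript sequence and are reported as
#' `otherLen`); subject sequence outside the terminal exons forms the
#' flanks.
#'
#' @param unigeneSeq spliced (query) sequence.
#' @param genespaceSeq genomic (subject) sequence.
#' @param evalueMax HSP e-value cutoff (default 1e-6).
#' @param qGapTol query-gap tolerance separating introns from alignment
#'   slippage (default 10 bp).
#' @return list of class `GeneStructure`: `exons` (data.frame start, end,
#'   identity; 1-based closed subject coordinates), `introns` (data.frame
#'   start, end), `flankUp`, `flankDown`, `otherLen`, `strand`, `nExons`,
#'   `nIntrons`, `meanIdentity`. Zero-exon structures (no HSP) warn.
#' @export
inferStructure <- function(unigeneSeq, genespaceSeq, evalueMax = 1e-6,
                           qGapTol = 10L) {
  q <- as.character(unigeneSeq)
  s <- as.character(genespaceSeq)
  stopifnot(nchar(q) > 0, nchar(s) > 0)
  empty <- function() {
    warning("no qualifying HSP; returning a zero-exon structure")
    structure(list(exons = data.frame(start = integer(0), end = integer(0),
                                      identity = numeric(0)),
                   introns = data.frame(start = integer(0), end = integer(0)),
                   flankUp = 0L, flankDown = 0L, otherLen = nchar(s),
                   strand = NA_character_, nExons = 0L, nIntrons = 0L,
                   meanIdentity = NA_real_, subjectLen = nchar(s)),
              class = "GeneStructure")
  }
  h <- nucHsps(q, s)
  h <- h[h$evalue <= evalueMax, , drop = FALSE]
  if (nrow(h) == 0) return(empty())
  strandScore <- tapply(h$score, h$strand, sum)
  keepStrand <- names(strandScore)[which.max(strandScore)]
  h <- h[h$strand == keepStrand, , drop = FALSE]
  chain <- chainHsps(h)
  h <- h[chain, , drop = FALSE]
  # trim overlaps between consecutive chain members at the overlap midpoint,
  # shifting query and subject ends together so HSPs stay on their diagonals
  n <- nrow(h)
  if (n > 1) {
    for (j in 2:n) {
      oq <- h$qend[j - 1] - h$qstart[j] + 1L
      os <- h$send[j - 1] - h$sstart[j] + 1L
      o <- max(oq, os, 0L)
      if (o > 0) {
        a <- as.integer(ceiling(o / 2)); b <- o - a
        h$qend[j - 1] <- h$qend[j - 1] - a
        h$send[j - 1] <- h$send[j - 1] - a
        h$qstart[j] <- h$qstart[j] + b
        h$sstart[j] <- h$sstart[j] + b
      }
    }
  }
  identity <- h$matches / h$length  # trim keeps identity representative
  exons <- data.frame(start = h$sstart, end = h$send, identity = identity)
  introns <- data.frame(start = integer(0), end = integer(0))
  otherLen <- 0L
  if (n > 1) {
    for (j in 2:n) {
      sGap <- h$sstart[j] - h$send[j - 1] - 1L
      qGap <- h$qstart[j] - h$qend[j - 1] - 1L
      if (sGap <= 0) next
      if (qGap <= qGapTol) {
        introns <- rbind(introns, data.frame(start = h$send[j - 1] + 1L,
                                             end = h$sstart[j] - 1L))
      } else {
        otherLen <- otherLen + sGap
      }
    }
  }
  structure(list(exons = exons, introns = introns,
                 flankUp = min(h$sstart) - 1L,
                 flankDown = nchar(s) - max(h$send),
                 otherLen = otherLen, strand = keepStrand,
                 nExons = nrow(exons), nIntrons = nrow(introns),
                 meanIdentity = sum(h$matches) / sum(h$length),
                 subjectLen = nchar(s)),
            class = "GeneStructure")
}

#' @export
print.GeneStructure <- function(x, ...) {
  cat("GeneStructure:", x$nExons, "exons,", x$nIntrons, "introns,",
      "flanks", x$flankUp, "/", x$flankDown, "bp, mean identity",
      if (is.na(x$meanIdentity)) "NA" else sprintf("%.1f%%",
                                                   100 * x$meanIdentity), "\n")
  invisible(x)
}

#' Summarize exon/intron distributions over structures
#'
#' @param structures list of `GeneStructure` objects.
#' @return data.frame with one row per feature class (exon count, intron
#'   count, exon length, intron length): min, max, mean, median, n.
#' @export
structureSummary <- function(structures) {
  stopifnot(length(structures) >= 1)
  exCounts <- vapply(structures, function(s) s$nExons, integer(1))
  inCounts <- vapply(structures, function(s) s$nIntrons, integer(1))
  exLens <- unlist(lapply(structures, function(s)
    if (s$nExons) s$exons$end - s$exons$start + 1L else integer(0)))
  inLens <- unlist(lapply(structures, function(s)
    if (s$nIntrons) s$introns$end - s$introns$start + 1L else integer(0)))
  row <- function(feature, x) {
    if (length(x) == 0)
      return(data.frame(feature = feature, min = NA_real_, max = NA_real_,
                        mean = NA_real_, median = NA_real_, n = 0L))
    data.frame(feature = feature, min = min(x), max = max(x),
               mean = mean(x), median = stats::median(x), n = length(x))
  }
  rbind(row("exons_per_sequence", exCounts),
        row("introns_per_sequence", inCounts),
        row("exon_length", exLens),
        row("intron_length", inLens))
}
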