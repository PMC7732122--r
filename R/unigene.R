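#' Translated homology search of contigs against a protein set
#'
#' All six reading frames of every contig are aligned locally
#' (Smith-Waterman, BLOSUM62, gap open 11 / extend 1) against candidate
#' proteins sharing at least one 5-residue word with the frame. Scores are
#' converted to e-values with gapped Karlin-Altschul statistics (lambda
#' 0.267, K 0.041, the published BLASTX defaults) over an effective space of
#' frame length x database residues. Coverage is measured on the protein
#' (the fraction of the best hit covered by the contig), identity over the
#' aligned columns.
#'
#' @param contigs `DNAStringSet`.
#' @param proteins `AAStringSet` reference protein set.
#' @param evalueMax e-value cutoff (default 1e-20).
#' @return data.frame: contig, protein, frame, identityPct, coveragePct,
#'   score, bitScore, evalue — all hits passing the cutoff.
#' @export
translatedSearch <- function(contigs, proteins, evalueMax = 1e-20) {
  if (length(proteins) == 0) stop("protein set is empty")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  dbLen <- sum(width(proteins))
  lambda <- 0.267; K <- 0.041
  word <- 5L
  protWords <- new.env(parent = emptyenv())
  protChar <- as.character(proteins)
  for (j in seq_along(protChar)) {
    p <- protChar[j]
    if (nchar(p) < word) next
    ws <- unique(substring(p, 1:(nchar(p) - word + 1), word:nchar(p)))
    for (w in ws) assign(w, c(protWords[[w]], j), envir = protWords)
  }
  out <- list()
  cid <- names(contigs)
  if (is.null(cid)) cid <- sprintf("contig%05d", seq_along(contigs))
  for (i in seq_along(contigs)) {
    s <- as.character(contigs[[i]])
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      seq <- if (fr > 0) s else as.character(reverseComplement(DNAString(s)))
      off <- abs(fr) - 1L
      n <- nchar(seq) - off
      n <- n - (n %% 3L)
      if (n < 3 * word) next
      aa <- suppressWarnings(as.character(
        translate(DNAString(substr(seq, off + 1L, off + n)),
                  if.fuzzy.codon = "X")))
      m <- nchar(aa)
      ws <- unique(substring(aa, 1:(m - word + 1), word:m))
      cands <- sort(unique(unlist(mget(ws, envir = protWords,
                                       ifnotfound = list(NULL)))))
      for (j in cands) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(aa), proteins[[j]], type = "local",
          substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
        S <- Biostrings::score(pa)
        bits <- (lambda * S - log(K)) / log(2)
        ev <- m * dbLen * 2^(-bits)
        if (ev > evalueMax) next
        sCov <- 100 * (Biostrings::end(Biostrings::subject(pa)) -
                         Biostrings::start(Biostrings::subject(pa)) + 1) /
          width(proteins)[j]
        out[[length(out) + 1L]] <- data.frame(
          contig = cid[i], protein = names(proteins)[j], frame = fr,
          identityPct = Biostrings::pid(pa),
          coveragePct = sCov, score = S, bitScore = bits, evalue = ev)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), protein = character(0),
                      frame = integer(0), identityPct = numeric(0),
                      coveragePct = numeric(0), score = numeric(0),
                      bitScore = numeric(0), evalue = numeric(0)))
  do.call(rbind, out)
}

# best hit per contig: lowest e-value, ties by higher bit score, then
# lexicographic protein id
bestHits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$contig, hits$evalue, -hits$bitScore, hits$protein)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$contig), , drop = FALSE]
}

#' Build the non-redundant Unigene
#'
#' Contigs whose best hit covers more than `minCov` percent of the protein
#' with more than `minIdent` percent identity are eligible. Within an
#' assembly, one contig is kept per best-hit protein (the longest); across
#' assemblies sharing a best hit the longest form wins, with ties broken by
#' the higher alignment identity. The result is non-redundant: one record
#' per protein.
#'
#' @param hitSets named list (per assembly) of [translatedSearch()] tables.
#' @param contigSets named list (same names) of contig `DNAStringSet`s.
#' @param minCov,minIdent selection thresholds (70, 30; strict inequalities).
#' @return `DNAStringSet` named `UG0001...`, ordered by protein id, with
#'   metadata columns bbhProtein, sourceAssembly, sourceContig, coveragePct,
#'   identityPct.
#' @export
buildUnigene <- function(hitSets, contigSets, minCov = 70, minIdent = 30) {
  stopifnot(identical(names(hitSets), names(contigSets)))
  rows <- list()
  for (asm in names(hitSets)) {
    h <- bestHits(hitSets[[asm]])
    h <- h[h$coveragePct > minCov & h$identityPct > minIdent, , drop = FALSE]
    if (nrow(h) == 0) next
    ctg <- contigSets[[asm]]
    h$len <- width(ctg)[match(h$contig, names(ctg))]
    h$assembly <- asm
    # within-assembly redundancy: keep the longest contig per protein
    o <- order(h$protein, -h$len, -h$identityPct, h$contig)
    h <- h[o, , drop = FALSE]
    rows[[asm]] <- h[!duplicated(h$protein), , drop = FALSE]
  }
  if (length(rows) == 0) {
    warning("no contig passed the Unigene thresholds")
    return(DNAStringSet())
  }
  all <- do.call(rbind, rows)
  # across assemblies: longest form, ties by higher identity
  o <- order(all$protein, -all$len, -all$identityPct,
             match(all$assembly, names(hitSets)), all$contig)
  all <- all[o, , drop = FALSE]
  all <- all[!duplicated(all$protein), , drop = FALSE]
  seqs <- DNAStringSet(vapply(seq_len(nrow(all)), function(i)
    as.character(contigSets[[all$assembly[i]]][[all$contig[i]]]),
    character(1)))
  names(seqs) <- sprintf("UG%04d", seq_len(nrow(all)))
  S4Vectors::mcols(seqs)$bbhProtein <- all$protein
  S4Vectors::mcols(seqs)$sourceAssembly <- all$assembly
  S4Vectors::mcols(seqs)$sourceContig <- all$contig
  S4Vectors::mcols(seqs)$coveragePct <- all$coveragePct
  S4Vectors::mcols(seqs)$identityPct <- all$identityPct
  seqs
}

#' Remove flagged records from the Unigene
#'
#' @param unigene `DNAStringSet` (as from [buildUnigene()]).
#' @param flaggedIds ids to remove; unknown ids warn and are skipped.
#' @return the cleaned `DNAStringSet`; message reports the removal count.
#' @export
purgeContaminants <- function(unigene, flaggedIds) {
  unknown <- setdiff(flaggedIds, names(unigene))
  if (length(unknown))
    warning("unknown ids skipped: ", paste(unknown, collapse = ", "))
  drop <- names(unigene) %in% flaggedIds
  out <- unigene[!drop]
  message(sum(drop), " record(s) purged from the Unigene")
  if (length(out) == 0) warning("all Unigene records were purged")
  out
}
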