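#' Map paired reads to reference sequences
#'
#' Seed-and-extend mapping with CLC-like acceptance semantics: a placement is
#' accepted when the aligned fraction of the read reaches `lengthFraction`
#' AND its identity over the aligned span reaches `similarityFraction`.
#' A read whose best placement score is tied by a second placement is marked
#' non-specific (`specific = FALSE`) and treated as unmapped downstream.
#' Pair status is `intact` when both mates map to the same reference in
#' opposite orientations with an insert inside the window (mean +/- 4 sd,
#' estimated from the mapped pairs when not supplied), `broken` when exactly
#' one mate maps, `unmapped` otherwise.
#'
#' @param pair list with `r1`, `r2` read sets.
#' @param refs `DNAStringSet` of references.
#' @param lengthFraction,similarityFraction acceptance thresholds in (0, 1].
#' @param insertMean,insertSd optional insert-size window parameters.
#' @return list: `m1`, `m2` (data.frames: read, ref, pos, strand, frac,
#'   identity, specific, accepted), `pairStatus` (character per pair),
#'   `insertMean`, `insertSd`.
#' @export
mapReads <- function(pair, refs, lengthFraction = 1.0,
                     similarityFraction = 0.95,
                     insertMean = NULL, insertSd = NULL) {
  stopifnot(lengthFraction > 0, lengthFraction <= 1,
            similarityFraction > 0, similarityFraction <= 1)
  refChar <- as.character(refs)
  one <- function(reads) {
    s <- as.character(reads)
    if (length(refChar) == 0 || length(s) == 0) {
      return(data.frame(read = names(reads), ref = integer(length(s)),
                        pos = integer(length(s)),
                        strand = rep("+", length(s)),
                        frac = numeric(length(s)),
                        identity = numeric(length(s)),
                        specific = logical(length(s)),
                        accepted = logical(length(s))))
    }
    d <- map_reads_cpp(s, refChar, 15L, 10L, 100L, 64L)
    L <- nchar(s)
    frac <- ifelse(L > 0, d$overlap / L, 0)
    identity <- ifelse(d$overlap > 0, d$matches / d$overlap, 0)
    specific <- d$matches > d$second
    accepted <- d$ref > 0 & frac >= lengthFraction - 1e-9 &
      identity >= similarityFraction - 1e-9 & specific
    data.frame(read = names(reads), ref = d$ref, pos = d$pos,
               strand = d$strand, frac = frac, identity = identity,
               specific = specific, accepted = accepted)
  }
  m1 <- one(pair$r1)
  m2 <- one(pair$r2)
  sameRef <- m1$accepted & m2$accepted & m1$ref == m2$ref &
    m1$strand != m2$strand
  ins <- rep(NA_real_, nrow(m1))
  if (any(sameRef)) {
    l1 <- width(pair$r1)[sameRef]; l2 <- width(pair$r2)[sameRef]
    left <- pmin(m1$pos[sameRef], m2$pos[sameRef])
    right <- pmax(m1$pos[sameRef] + l1 - 1L, m2$pos[sameRef] + l2 - 1L)
    ins[sameRef] <- right - left + 1L
  }
  if (is.null(insertMean)) {
    obs <- ins[!is.na(ins)]
    obs <- utils::head(obs, 10000L)
    insertMean <- if (length(obs)) mean(obs) else 0
    insertSd <- if (length(obs) > 1) stats::sd(obs) else insertMean
  }
  if (is.null(insertSd)) insertSd <- insertMean / 10
  window <- c(insertMean - 4 * max(insertSd, 1),
              insertMean + 4 * max(insertSd, 1))
  intact <- sameRef & !is.na(ins) & ins >= window[1] & ins <= window[2]
  status <- ifelse(intact, "intact",
                   ifelse(xor(m1$accepted, m2$accepted) |
                            (m1$accepted & m2$accepted & !intact), "broken",
                          "unmapped"))
  list(m1 = m1, m2 = m2, pairStatus = status,
       insertMean = insertMean, insertSd = insertSd)
}

#' Extract recruited read pairs
#'
#' Both mates of intact pairs AND both mates of broken pairs (the mapped mate
#' and its unmapped partner) are extracted; rescuing the unmapped mate of a
#' broken pair is what lets the guided assembly walk into introns and past
#' contig ends. Fully unmapped pairs are dropped.
#'
#' @param mapRes result of [mapReads()].
#' @param pair the read pair list that was mapped.
#' @return list `r1`, `r2` restricted to recruited pairs.
#' @export
extractRecruited <- function(mapRes, pair) {
  keep <- mapRes$pairStatus %in% c("intact", "broken")
  list(r1 = pair$r1[keep], r2 = pair$r2[keep])
}

#' Multi-k guided de Bruijn assembly
#'
#' Assembles the recruited reads at k = `kmin`, `kmin + kstep`, ..., `kmax`;
#' at every k the contigs of the previous k together with the guide
#' sequences are injected as trusted pseudo-reads whose k-mers are exempt
#' from coverage pruning, so information assembled earlier is preserved while
#' new sequence accretes.
#'
#' @param recruited list `r1`, `r2` of recruited reads.
#' @param guides `DNAStringSet` of guide sequences (may be empty / NULL).
#' @param kmin,kmax,kstep k-mer ladder (defaults 25, 100, 5).
#' @param minCount coverage cutoff for non-trusted k-mers.
#' @param minLen minimum length of returned contigs.
#' @return `DNAStringSet` of contigs.
#' @export
guidedAssemble <- function(recruited, guides = NULL, kmin = 25L, kmax = 100L,
                           kstep = 5L, minCount = 2L, minLen = 200L) {
  stopifnot(kmin <= kmax)
  guideChar <- if (is.null(guides)) character(0) else as.character(guides)
  reads <- c(as.character(recruited$r1), as.character(recruited$r2))
  if (length(reads) == 0) {
    warning("no recruited reads; returning guides unchanged")
    out <- DNAStringSet(guideChar)
    if (length(out)) names(out) <- sprintf("c%06d", seq_along(out))
    return(out)
  }
  contigs <- character(0)
  for (k in seq(kmin, kmax, by = kstep)) {
    usable <- reads[nchar(reads) >= k]
    if (length(usable) == 0) break
    res <- dbg_assemble_cpp(usable, usable, as.integer(k),
                            as.integer(minCount),
                            as.integer(max(k + 11L, 100L)),
                            c(guideChar, contigs))
    contigs <- res$seq
  }
  contigs <- contigs[nchar(contigs) >= minLen]
  out <- DNAStringSet(contigs)
  if (length(out)) names(out) <- sprintf("c%06d", seq_along(out))
  out
}

#' Iterative Unigene-guided genomic assembly
#'
#' Iteration 1 maps the genomic reads to the Unigene at
#' (`lengthFraction` = 1, similarity `sim1` = 0.95, the lenient setting that
#' tolerates exon/intron junction mates); later iterations map the full read
#' set to the previous iteration's contigs at similarity `simN` = 0.98.
#' Recruited pairs (intact + broken) are assembled with the multi-k guided
#' assembler, the previous contigs acting as guides from iteration 2 onward.
#' After each iteration the number of rebuilt Unigene sequences — those whose
#' maximal collinear HSP chain against a single contig (nucleotide
#' alignment, e-value <= `evalueMax`) covers at least 90\% of the sequence —
#' is recorded; iterations stop when this count fails to increase, or at
#' `maxIter`.
#'
#' @param unigene `DNAStringSet` of Unigene sequences.
#' @param pair genomic read pair list of the reference clone.
#' @param maxIter maximum number of iterations (default 8).
#' @param sim1,simN similarity thresholds for iteration 1 / later iterations.
#' @param kmin,kmax,kstep multi-k ladder for the guided assembly.
#' @param evalueMax nucleotide-alignment cutoff for the rebuilt count.
#' @return list of iteration states: each has `iteration`, `contigs`,
#'   `rebuiltCount`, `recruitedReads`.
#' @export
iterateGenespace <- function(unigene, pair, maxIter = 8L, sim1 = 0.95,
                             simN = 0.98, kmin = 25L, kmax = 100L, kstep = 5L,
                             evalueMax = 1e-6) {
  stopifnot(maxIter >= 1)
  states <- list()
  contigs <- NULL
  uniChar <- as.character(unigene)
  for (it in seq_len(maxIter)) {
    refs <- if (it == 1) unigene else contigs
    sim <- if (it == 1) sim1 else simN
    mp <- mapReads(pair, refs, lengthFraction = 1.0, similarityFraction = sim)
    rec <- extractRecruited(mp, pair)
    newContigs <- guidedAssemble(rec, guides = if (it == 1) NULL else contigs,
                                 kmin = kmin, kmax = kmax, kstep = kstep)
    if (length(newContigs) == 0 && !is.null(contigs)) newContigs <- contigs
    # a Unigene sequence counts as rebuilt when one contig's collinear HSP
    # chain covers at least 90% of it — per-exon fragments do not qualify,
    # so the count keeps growing while introns are being bridged
    rebuilt <- sum(vapply(uniChar, function(u)
      length(newContigs) > 0 &&
        bestChainCoverage(u, newContigs, evalueMax) >= 0.9,
      logical(1)))
    states[[it]] <- list(iteration = it, contigs = newContigs,
                         rebuiltCount = rebuilt,
                         recruitedReads = 2L * length(rec$r1))
    contigs <- newContigs
    if (it > 1 && rebuilt <= states[[it - 1]]$rebuiltCount) break
    if (length(rec$r1) == 0) break
  }
  states
}

#' Compose the Genespace reference
#'
#' Every Unigene sequence is represented in its longest form: when a final
#' DNA contig matches it (nucleotide HSPs at e-value <= `evalueMax`) and is
#' longer than the RNA form, the DNA contig is used; otherwise the RNA form
#' is carried over verbatim (so sequences missing from the DNA assembly are
#' not lost). A DNA contig matching several Unigene sequences is emitted
#' once with all member ids (the concatenated case). The report classifies
#' every Unigene sequence as longer / concatenated / shorter / unmatched.
#'
#' @param unigene `DNAStringSet` of Unigene sequences.
#' @param finalContigs `DNAStringSet` from the last iteration.
#' @param evalueMax nucleotide-alignment cutoff.
#' @return list: `genespace` (`DNAStringSet` with metadata columns `members`
#'   (comma-joined Unigene ids) and `origin`), `report` (data.frame per
#'   Unigene sequence: unigene_id, class, contig, contigLen, rnaLen).
#' @export
composeGenespace <- function(unigene, finalContigs, evalueMax = 1e-6) {
  nU <- length(unigene)
  uid <- names(unigene)
  if (is.null(uid)) uid <- sprintf("u%04d", seq_len(nU))
  bestContig <- integer(nU)
  for (i in seq_len(nU)) {
    h <- nucHsps(as.character(unigene[[i]]), finalContigs)
    h <- h[h$evalue <= evalueMax, , drop = FALSE]
    if (nrow(h) == 0) next
    tot <- tapply(h$matches, h$subject, sum)
    bestContig[i] <- as.integer(names(tot)[which.max(tot)])
  }
  rnaLen <- width(unigene)
  ctgLen <- ifelse(bestContig > 0, width(finalContigs)[bestContig], 0L)
  useDna <- bestContig > 0 & ctgLen > rnaLen
  class <- ifelse(bestContig == 0, "unmatched",
                  ifelse(!useDna, "shorter", "longer"))
  # a used DNA contig claimed by several Unigene sequences => concatenated
  usedTab <- table(bestContig[useDna])
  shared <- as.integer(names(usedTab)[usedTab >= 2])
  class[useDna & bestContig %in% shared] <- "concatenated"
  seqs <- character(0); members <- character(0); origin <- character(0)
  emitted <- integer(0)
  for (i in seq_len(nU)) {
    if (useDna[i]) {
      ct <- bestContig[i]
      if (ct %in% emitted) {
        j <- match(ct, emitted)
        members[j] <- paste(members[j], uid[i], sep = ",")
      } else {
        emitted <- c(emitted, ct)
        seqs <- c(seqs, as.character(finalContigs[[ct]]))
        members <- c(members, uid[i])
        origin <- c(origin, "dna_contig")
      }
    } else {
      emitted <- c(emitted, NA_integer_)
      seqs <- c(seqs, as.character(unigene[[i]]))
      members <- c(members, uid[i])
      origin <- c(origin, "rna_contig")
    }
  }
  gs <- DNAStringSet(seqs)
  names(gs) <- sprintf("GS%04d", seq_along(gs))
  S4Vectors::mcols(gs)$members <- members
  S4Vectors::mcols(gs)$origin <- origin
  list(genespace = gs,
       report = data.frame(unigene_id = uid, class = class,
                           contig = ifelse(bestContig > 0,
                                           names(finalContigs)[bestContig],
                                           NA_character_),
                           contigLen = ctgLen, rnaLen = rnaLen))
}
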