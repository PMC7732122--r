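#' @importFrom Biostrings DNAStringSet AAStringSet DNAString PhredQuality
#'   QualityScaledDNAStringSet readQualityScaledDNAStringSet
#'   writeQualityScaledXStringSet writeXStringSet readDNAStringSet
#'   readAAStringSet reverseComplement translate subseq replaceLetterAt width
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats rnbinom rlnorm rnorm rpois runif rbinom
NULL

randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Sample exon/intron architectures
#'
#' Draws gene architectures from the configured laws: exon count is a shifted
#' negative binomial truncated to `[1, exonCountMax]` (mean 3, median 2 under
#' defaults), exon and intron lengths are rounded log-normals clamped at the
#' configured minima. Exposed separately from [generateGenome()] so the laws
#' can be checked at large n without building sequence.
#'
#' @param cfg a [SimConfig-class].
#' @param n number of genes to draw.
#' @return list with `exonLens` and `intronLens`, one integer vector per gene.
#' @export
sampleGeneArchitecture <- function(cfg, n) {
  m <- pmin(1L + rnbinom(n, size = cfg@exonCountSize, mu = cfg@exonCountMu),
            cfg@exonCountMax)
  exonLens <- lapply(m, function(k) {
    len <- pmax(as.integer(round(rlnorm(k, cfg@exonMeanLog, cfg@exonSdLog))),
                cfg@minExonLen)
    tot <- sum(len)
    if (tot < cfg@minTranscriptLen)  # pad the largest exon up to a viable mRNA
      len[which.max(len)] <- len[which.max(len)] + (cfg@minTranscriptLen - tot)
    len
  })
  intronLens <- lapply(m, function(k) {
    if (k < 2) return(integer(0))
    pmax(as.integer(round(rlnorm(k - 1, cfg@intronMeanLog, cfg@intronSdLog))),
         cfg@minIntronLen)
  })
  list(exonLens = exonLens, intronLens = intronLens)
}

# stop-free random codons for the planted CDS
randCodons <- function(n) {
  codons <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
    c("A", "C", "G", "T"), paste0)), c("A", "C", "G", "T"), paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

#' Generate a founder genome with gene models and reference proteins
#'
#' Builds one scaffold per gene: flank + exon/intron structure + flank. The
#' spliced transcript carries a planted coding sequence (ATG, stop-free
#' codons, stop) flanked by UTRs; its translation is the reference protein
#' set consumed by [translatedSearch()]. The last `nDecoys` genes are marked
#' as decoys: they appear among transcripts and proteins but are excluded
#' from clone genomes, emulating contaminant transcripts.
#'
#' @param cfg a [SimConfig-class]; `cfg@seed` fully determines the output.
#' @return A [SimGenome-class].
#' @examples
#' g <- generateGenome(simConfig(nGenes = 3, seed = 7))
#' g
#' @export
generateGenome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  nTot <- cfg@nGenes + cfg@nDecoys
  arch <- sampleGeneArchitecture(cfg, nTot)
  geneIds <- c(sprintf("g%04d", seq_len(cfg@nGenes)),
               if (cfg@nDecoys > 0) sprintf("decoy%03d", seq_len(cfg@nDecoys)))
  scafIds <- paste0("scf_", geneIds)
  scafSeq <- character(nTot)
  txSeq <- character(nTot)
  protSeq <- character(nTot)
  exL <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    exons <- arch$exonLens[[i]]
    introns <- arch$intronLens[[i]]
    if (i > cfg@nGenes && sum(exons) < 400L) {
      # decoy transcripts get a 400 bp floor so contaminant carry-over into
      # the Unigene (and its later flagging) is actually exercised
      exons[which.max(exons)] <- exons[which.max(exons)] + (400L - sum(exons))
    }
    tlen <- sum(exons)
    utr5 <- as.integer(floor(cfg@utrFrac * tlen))
    utr3 <- as.integer(floor(cfg@utrFrac * tlen))
    cdsLen <- tlen - utr5 - utr3
    cdsLen <- cdsLen - (cdsLen %% 3L)
    nCod <- cdsLen %/% 3L
    cds <- paste0("ATG", randCodons(nCod - 2L), sample(c("TAA", "TAG", "TGA"), 1))
    u5 <- randDna(utr5)
    if (utr5 >= 3L)  # in-frame stop just upstream keeps the CDS the longest ORF
      substr(u5, utr5 - 2L, utr5) <- "TAA"
    tx <- paste0(u5, cds, randDna(tlen - utr5 - cdsLen))
    intronSeq <- vapply(introns, function(L) {
      if (cfg@spliceMotifs && L >= 4) paste0("GT", randDna(L - 4L), "AG")
      else randDna(L)
    }, character(1))
    # interleave exon slices of the transcript with introns (sense orientation)
    ends <- cumsum(exons)
    starts <- ends - exons + 1L
    pieces <- character(2 * length(exons) - 1)
    pieces[seq_along(exons) * 2 - 1] <- substring(tx, starts, ends)
    if (length(introns)) pieces[seq_along(introns) * 2] <- intronSeq
    gene <- paste(pieces, collapse = "")
    strand <- sample(c("+", "-"), 1)
    body <- if (strand == "+") gene else
      as.character(reverseComplement(DNAString(gene)))
    scafSeq[i] <- paste0(randDna(cfg@flankLen), body, randDna(cfg@flankLen))
    txSeq[i] <- tx
    protSeq[i] <- as.character(translate(DNAString(substr(cds, 1, cdsLen - 3L))))
    # exon coordinates on the scaffold (1-based closed)
    G <- nchar(gene)
    gStarts <- starts + c(0L, cumsum(introns))[seq_along(exons)]
    gEnds <- gStarts + exons - 1L
    if (strand == "+") {
      s <- cfg@flankLen + gStarts
      e <- cfg@flankLen + gEnds
    } else {
      s <- cfg@flankLen + (G - gEnds) + 1L
      e <- cfg@flankLen + (G - gStarts) + 1L
    }
    exL[[i]] <- data.frame(seqid = scafIds[i], start = s, end = e,
                           strand = strand, gene_id = geneIds[i],
                           exon_rank = seq_along(exons),
                           decoy = i > cfg@nGenes)
  }
  ex <- do.call(rbind, exL)
  gr <- GRanges(ex$seqid, IRanges(ex$start, ex$end), strand = ex$strand,
                gene_id = ex$gene_id, exon_rank = ex$exon_rank,
                decoy = ex$decoy)
  scaffolds <- DNAStringSet(scafSeq); names(scaffolds) <- scafIds
  txs <- DNAStringSet(txSeq); names(txs) <- geneIds
  prot <- AAStringSet(protSeq); names(prot) <- geneIds
  new("SimGenome", scaffolds = scaffolds, exons = gr,
      transcripts = txs, proteins = prot, config = cfg)
}

#' Derive a heterozygous clone panel from a founder genome
#'
#' Segregating sites are planted per bp at `cfg@snpRate`; at each site every
#' clone draws a genotype with `P(het) = cfg@hetProb` (hom-ref and hom-alt
#' split the remainder), reflecting the excess heterozygosity of clonally
#' propagated outbreeders, and the alleles are phased onto the clone's two
#' haplotypes. The first clone is the reference clone (the Maillette
#' analogue); per-clone DNA depths spread over the configured range with the
#' reference clone at the maximum.
#'
#' @param genome a [SimGenome-class].
#' @param cfg the [SimConfig-class] used to build it.
#' @param nClones number of clones (>= 2).
#' @return A [ClonePanel-class].
#' @export
generateClonePanel <- function(genome, cfg, nClones) {
  stopifnot(is(genome, "SimGenome"))
  if (nClones < 2) stop("a clone panel needs at least 2 clones")
  set.seed(cfg@seed + 1L)
  decoyGene <- vapply(split(S4Vectors::mcols(genome@exons)$decoy,
                            S4Vectors::mcols(genome@exons)$gene_id),
                      any, logical(1))
  keep <- !names(genome@scaffolds) %in%
    paste0("scf_", names(decoyGene)[decoyGene])
  scaffolds <- genome@scaffolds[keep]
  seqid <- character(0); pos <- integer(0)
  for (i in seq_along(scaffolds)) {
    L <- width(scaffolds)[i]
    at <- which(runif(L) < cfg@snpRate)
    seqid <- c(seqid, rep(names(scaffolds)[i], length(at)))
    pos <- c(pos, at)
  }
  nS <- length(pos)
  ref <- character(nS); alt <- character(nS)
  if (nS > 0) {
    scafChar <- as.character(scaffolds)
    ref <- substring(scafChar[seqid], pos, pos)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
      USE.NAMES = FALSE)
  }
  clones <- sprintf("clone%02d", seq_len(nClones))
  h <- cfg@hetProb
  codes <- matrix(sample(c(0L, 1L, 2L), nS * nClones, replace = TRUE,
                         prob = c((1 - h) / 2, h, (1 - h) / 2)),
                  nrow = nS, ncol = nClones, dimnames = list(NULL, clones))
  hap1 <- matrix(FALSE, nS, nClones, dimnames = list(NULL, clones))
  hap2 <- hap1
  if (nS > 0) {
    hetFlip <- matrix(runif(nS * nClones) < 0.5, nS, nClones)
    hap1 <- (codes == 2L) | (codes == 1L & hetFlip)
    hap2 <- (codes == 2L) | (codes == 1L & !hetFlip)
    dimnames(hap1) <- dimnames(hap2) <- list(NULL, clones)
  }
  depths <- if (length(cfg@dnaDepth) == nClones) cfg@dnaDepth
    else if (length(cfg@dnaDepth) == 1) rep(cfg@dnaDepth, nClones)
    else rev(seq(min(cfg@dnaDepth), max(cfg@dnaDepth), length.out = nClones))
  new("ClonePanel", scaffolds = scaffolds,
      truth = DataFrame(seqid = seqid, pos = pos, ref = ref, alt = alt),
      hap1 = hap1, hap2 = hap2, clones = clones,
      referenceClone = clones[1], depths = depths)
}

#' Rebuild the two haplotype sequences of a clone
#'
#' Applies the clone's alt alleles to the reference scaffolds; this is the
#' same path used by read simulation, so truth files and emitted sequence are
#' consistent by construction (and tested as such).
#'
#' @param panel a [ClonePanel-class].
#' @param clone clone identifier.
#' @return list of two `DNAStringSet`s, `hap1` and `hap2`.
#' @export
cloneHaplotypes <- function(panel, clone) {
  stopifnot(clone %in% panel@clones)
  applyHap <- function(carry) {
    out <- panel@scaffolds
    idx <- which(carry)
    if (length(idx)) {
      bySc <- split(idx, panel@truth$seqid[idx])
      for (sc in names(bySc)) {
        j <- bySc[[sc]]
        out[[sc]] <- replaceLetterAt(out[[sc]], panel@truth$pos[j],
                                     paste(panel@truth$alt[j], collapse = ""))
      }
    }
    out
  }
  list(hap1 = applyHap(panel@hap1[, clone]),
       hap2 = applyHap(panel@hap2[, clone]))
}

# linear 40->30 mean Phred with Gaussian jitter; returns integer matrix n x L
sampleQualities <- function(n, L, cfg) {
  mu <- seq(cfg@qStart, cfg@qEnd, length.out = L)
  q <- matrix(rep(mu, each = n), n, L) +
    matrix(rnorm(n * L, 0, cfg@qJitter), n, L)
  matrix(as.integer(pmax(2, pmin(41, round(q)))), n, L)
}

# apply the quality-driven substitution errors and N calls to a batch of
# equal-length read sequences; returns list(seq=character, qual=character)
mutateReads <- function(seqs, cfg) {
  n <- length(seqs)
  if (n == 0) return(list(seq = character(0), qual = character(0)))
  L <- nchar(seqs[1])
  q <- sampleQualities(n, L, cfg)
  perr <- if (is.na(cfg@errorRate)) 10^(-q / 10) else
    matrix(cfg@errorRate, n, L)
  errAt <- which(matrix(runif(n * L), n, L) < perr, arr.ind = TRUE)
  if (nrow(errAt)) {
    for (k in seq_len(nrow(errAt))) {
      i <- errAt[k, 1]; j <- errAt[k, 2]
      orig <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
    }
  }
  if (cfg@nRate > 0) {
    nAt <- which(matrix(runif(n * L), n, L) < cfg@nRate, arr.ind = TRUE)
    if (nrow(nAt)) {
      for (k in seq_len(nrow(nAt))) {
        i <- nAt[k, 1]; j <- nAt[k, 2]
        substr(seqs[i], j, j) <- "N"
        q[i, j] <- 2L
      }
    }
  }
  qual <- vapply(seq_len(n), function(i) rawToChar(as.raw(q[i, ] + 33L)),
                 character(1))
  list(seq = seqs, qual = qual)
}

asFastq <- function(seqs, quals, ids) {
  x <- QualityScaledDNAStringSet(DNAStringSet(seqs), PhredQuality(quals))
  names(x) <- ids
  x
}

# spliced transcript of one gene from a haplotype scaffold set
spliceTranscript <- function(hapScaffolds, exons, geneId) {
  sel <- exons[S4Vectors::mcols(exons)$gene_id == geneId]
  sel <- sel[order(S4Vectors::mcols(sel)$exon_rank)]
  sc <- hapScaffolds[[as.character(GenomicRanges::seqnames(sel)[1])]]
  parts <- vapply(seq_along(sel), function(i) {
    s <- as.character(subseq(sc, GenomicRanges::start(sel)[i],
                             GenomicRanges::end(sel)[i]))
    if (as.character(GenomicRanges::strand(sel)[i]) == "-")
      s <- as.character(reverseComplement(DNAString(s)))
    s
  }, character(1))
  paste(parts, collapse = "")
}

#' Simulate stranded RNA paired-end reads from the reference clone
#'
#' Fragments are drawn from the spliced transcripts of both haplotypes of the
#' reference clone (decoy transcripts from the founder), so reads never
#' contain intron sequence. The library is TruSeq-stranded: read 2 carries the
#' sense strand, read 1 its reverse complement; the protocol is recorded in
#' the FASTQ headers. Qualities follow the configured 40-to-30 profile and
#' errors are drawn per base from 10^(-Q/10).
#'
#' @param panel a [ClonePanel-class].
#' @param genome the matching [SimGenome-class].
#' @param cfg the [SimConfig-class].
#' @return list with `r1` and `r2` ([Biostrings::QualityScaledDNAStringSet]).
#' @export
simulateRnaReads <- function(panel, genome, cfg) {
  set.seed(cfg@seed + 2L)
  haps <- cloneHaplotypes(panel, panel@referenceClone)
  geneIds <- names(genome@transcripts)
  decoy <- !paste0("scf_", geneIds) %in% names(panel@scaffolds)
  frag1 <- character(0); frag2 <- character(0); ids <- character(0)
  readLen <- cfg@readLen
  cnt <- 0L
  for (gi in seq_along(geneIds)) {
    gid <- geneIds[gi]
    tx <- if (decoy[gi]) {
      list(as.character(genome@transcripts[[gid]]),
           as.character(genome@transcripts[[gid]]))
    } else {
      list(spliceTranscript(haps$hap1, genome@exons, gid),
           spliceTranscript(haps$hap2, genome@exons, gid))
    }
    len <- nchar(tx[[1]])
    if (len < readLen) next
    target <- rpois(1, cfg@rnaDepth * len / (2 * readLen))
    if (target == 0) next
    # molecule-wise fragmentation: each cDNA molecule is chopped into
    # consecutive fragments, so transcript ends are covered by the terminal
    # fragments of every molecule (fragments shorter than a read are lost)
    start <- integer(0); ins <- integer(0); hap <- integer(0)
    while (length(start) < target) {
      h <- sample(1:2, 1)
      pos <- 1L
      while (pos <= len - readLen + 1L) {
        flen <- max(readLen, as.integer(round(rnorm(1, cfg@insertMean,
                                                    cfg@insertSd))))
        end <- min(pos + flen - 1L, len)
        if (end - pos + 1L >= readLen) {
          start <- c(start, pos); ins <- c(ins, end - pos + 1L)
          hap <- c(hap, h)
        }
        pos <- end + 1L
      }
    }
    nFrag <- length(start)
    sense <- substring(tx[[1]], start, start + ins - 1L)
    h2 <- hap == 2
    if (any(h2))
      sense[h2] <- substring(tx[[2]], start[h2], start[h2] + ins[h2] - 1L)
    r2 <- substring(sense, 1L, readLen)
    r1 <- as.character(reverseComplement(DNAStringSet(
      substring(sense, ins - readLen + 1L, ins))))
    frag1 <- c(frag1, r1); frag2 <- c(frag2, r2)
    ids <- c(ids, sprintf("rna%06d gene=%s hap=%d proto=R2-sense",
                          cnt + seq_len(nFrag), gid, hap))
    cnt <- cnt + nFrag
  }
  m1 <- mutateReads(frag1, cfg)
  m2 <- mutateReads(frag2, cfg)
  list(r1 = asFastq(m1$seq, m1$qual, ids), r2 = asFastq(m2$seq, m2$qual, ids))
}

#' Simulate genomic DNA paired-end reads for panel clones
#'
#' Genome-wide fragments are drawn from both haplotypes of each clone
#' (haplotype chosen per fragment with probability 1/2) at the clone's
#' configured mean depth, with FR orientation and random physical mate order.
#'
#' @param panel a [ClonePanel-class].
#' @param cfg the [SimConfig-class].
#' @param clones subset of clone ids (default: all). Each clone has its own
#'   seeded stream, so per-clone output does not depend on the subset.
#' @return named list per clone of `list(r1, r2)`.
#' @export
simulateDnaReads <- function(panel, cfg, clones = NULL) {
  if (is.null(clones)) clones <- panel@clones
  readLen <- cfg@readLen
  out <- vector("list", length(clones))
  names(out) <- clones
  for (cl in clones) {
    ci <- match(cl, panel@clones)
    set.seed(cfg@seed + 1000L + ci)
    haps <- cloneHaplotypes(panel, cl)
    depth <- panel@depths[ci]
    frag1 <- character(0); frag2 <- character(0); ids <- character(0)
    cnt <- 0L
    for (sc in names(panel@scaffolds)) {
      L <- width(panel@scaffolds)[match(sc, names(panel@scaffolds))]
      if (L < readLen) next
      nFrag <- rpois(1, depth * L / (2 * readLen))
      if (nFrag == 0) next
      hap <- sample(1:2, nFrag, replace = TRUE)
      ins <- pmin(pmax(as.integer(round(rnorm(nFrag, cfg@insertMean,
                                              cfg@insertSd))), readLen), L)
      start <- vapply(ins, function(x) sample.int(L - x + 1L, 1), integer(1))
      s1 <- as.character(haps$hap1[[sc]]); s2 <- as.character(haps$hap2[[sc]])
      frag <- substring(ifelse(hap == 1, s1, s2), start, start + ins - 1L)
      fwd <- substring(frag, 1L, readLen)
      rev <- as.character(reverseComplement(DNAStringSet(
        substring(frag, ins - readLen + 1L, ins))))
      swap <- runif(nFrag) < 0.5
      r1 <- ifelse(swap, rev, fwd)
      r2 <- ifelse(swap, fwd, rev)
      frag1 <- c(frag1, r1); frag2 <- c(frag2, r2)
      ids <- c(ids, sprintf("%s_d%06d scf=%s hap=%d", cl,
                            cnt + seq_len(nFrag), sc, hap))
      cnt <- cnt + nFrag
    }
    m1 <- mutateReads(frag1, cfg)
    m2 <- mutateReads(frag2, cfg)
    out[[cl]] <- list(r1 = asFastq(m1$seq, m1$qual, ids),
                      r2 = asFastq(m2$seq, m2$qual, ids))
  }
  out
}

#' Write / read a FASTQ mate pair
#'
#' Thin wrappers over Biostrings' Phred+33 FASTQ support.
#'
#' @param pair list with elements `r1`, `r2`.
#' @param prefix output path prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return `writeFastqPair` the two paths, invisibly; `readFastqPair` a pair list.
#' @export
writeFastqPair <- function(pair, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  writeQualityScaledXStringSet(pair$r1, p1)
  writeQualityScaledXStringSet(pair$r2, p2)
  invisible(c(p1, p2))
}

#' @rdname writeFastqPair
#' @param f1,f2 FASTQ paths for mate 1 and mate 2.
#' @export
readFastqPair <- function(f1, f2) {
  # Biostrings warns about dropping its own internal metadata columns here
  list(r1 = suppressWarnings(readQualityScaledDNAStringSet(f1)),
       r2 = suppressWarnings(readQualityScaledDNAStringSet(f2)))
}

#' Write the panel truth variants as VCF v4.2
#'
#' Phased genotypes per clone (`0|1` style). Coordinates are 1-based as the
#' format requires; internal representations are documented per function.
#'
#' @param panel a [ClonePanel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruthVcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=orphangene-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel@clones), collapse = "\t")), con)
  tr <- panel@truth
  if (nrow(tr) > 0) {
    gt <- matrix("", nrow(tr), length(panel@clones))
    for (j in seq_along(panel@clones)) {
      gt[, j] <- paste0(as.integer(panel@hap1[, j]), "|",
                        as.integer(panel@hap2[, j]))
    }
    lines <- paste(tr$seqid, tr$pos, ".", tr$ref, tr$alt, ".", "PASS", ".",
                   "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Export gene models as GFF3
#'
#' One exon feature per row, 1-based closed intervals per the GFF3 standard.
#'
#' @param genome a [SimGenome-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportGeneModels <- function(genome, path) {
  gr <- genome@exons
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$ID <- paste0(S4Vectors::mcols(gr)$gene_id, ".e",
                                    S4Vectors::mcols(gr)$exon_rank)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
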