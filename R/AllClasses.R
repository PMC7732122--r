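#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Simulation configuration
#'
#' Holds every tunable of the synthetic diploid genome and read simulator.
#' Defaults reproduce the statistical structure reported for the lavender
#' gene space: exon counts with mean 3 and median 2 (range 1--24), log-normal
#' exon lengths (mean 288 bp, median 189 bp), log-normal intron lengths
#' (mean 235 bp, median 114 bp), one SNP per 90 bp, clonally maintained
#' excess heterozygosity (70\% heterozygous genotypes per clone), 2 x 150 bp
#' paired-end reads and per-clone depths spread over 5--25x.
#'
#' @slot nGenes number of real gene models.
#' @slot nDecoys number of decoy genes present in RNA (and in the protein set)
#'   but absent from every clone genome; they emulate contaminant transcripts.
#' @slot exonCountMu,exonCountSize shifted negative-binomial law for the exon
#'   count: \code{1 + rnbinom(size, mu)} truncated to \code{exonCountMax}.
#' @slot exonCountMax upper truncation of the exon count (24).
#' @slot exonMeanLog,exonSdLog log-normal exon length parameters.
#' @slot intronMeanLog,intronSdLog log-normal intron length parameters.
#' @slot minExonLen,minIntronLen lower clamps in bp (introns never below 20 bp;
#'   zero-length introns reported in real alignments are treated as artifacts).
#' @slot minTranscriptLen minimum spliced transcript length in bp.
#' @slot utrFrac fraction of the transcript assigned to each UTR.
#' @slot spliceMotifs decorate introns with canonical GT..AG dinucleotides.
#' @slot flankLen scaffold flank placed on each side of a gene, bp.
#' @slot snpRate per-bp probability that a gene-space site segregates (1/90).
#' @slot hetProb probability that a clone is heterozygous at a segregating
#'   site; clonal outbreeders retain non-Hardy-Weinberg excess heterozygosity.
#' @slot readLen read length before trimming (150).
#' @slot insertMean,insertSd fragment-size law, bp.
#' @slot rnaDepth RNA fold-coverage per transcript.
#' @slot dnaDepth either one value, a c(min, max) range spread across clones,
#'   or one value per clone; the reference clone receives the largest depth.
#' @slot qStart,qEnd,qJitter linear mean Phred profile along the read (40 to
#'   30) with Gaussian jitter; substitution errors are drawn per base from
#'   10^(-Q/10).
#' @slot nRate per-base probability of an ambiguous N call.
#' @slot errorRate optional fixed per-base substitution probability; when NA
#'   (default) errors follow the quality model.
#' @slot seed integer seed; it fully determines every simulator output.
#' @export
setClass("SimConfig", slots = c(
  nGenes = "integer", nDecoys = "integer",
  exonCountMu = "numeric", exonCountSize = "numeric", exonCountMax = "integer",
  exonMeanLog = "numeric", exonSdLog = "numeric",
  intronMeanLog = "numeric", intronSdLog = "numeric",
  minExonLen = "integer", minIntronLen = "integer", minTranscriptLen = "integer",
  utrFrac = "numeric", spliceMotifs = "logical", flankLen = "integer",
  snpRate = "numeric", hetProb = "numeric",
  readLen = "integer", insertMean = "numeric", insertSd = "numeric",
  rnaDepth = "numeric", dnaDepth = "numeric",
  qStart = "numeric", qEnd = "numeric", qJitter = "numeric", nRate = "numeric",
  errorRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (object@snpRate <= 0 || object@snpRate > 1)
    msg <- c(msg, "snpRate must be in (0, 1]")
  if (object@hetProb < 0 || object@hetProb > 1)
    msg <- c(msg, "hetProb must be in [0, 1]")
  if (object@readLen > object@insertMean)
    msg <- c(msg, "readLen must not exceed insertMean")
  if (any(object@dnaDepth <= 0) || object@rnaDepth <= 0)
    msg <- c(msg, "depths must be positive")
  if (object@utrFrac < 0 || object@utrFrac > 0.4)
    msg <- c(msg, "utrFrac must be in [0, 0.4]")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' See [SimConfig-class] for the meaning and provenance of every default.
#'
#' @param nGenes,nDecoys gene and decoy counts.
#' @param snpRate segregating-site density per bp.
#' @param hetProb per-clone heterozygosity at a segregating site.
#' @param readLen,insertMean,insertSd read/fragment geometry in bp.
#' @param rnaDepth,dnaDepth fold-coverages.
#' @param qStart,qEnd,qJitter quality profile (Phred).
#' @param nRate ambiguous-base rate.
#' @param errorRate fixed substitution rate overriding the quality model
#'   (NA: derive errors from qualities).
#' @param seed integer seed.
#' @param ... remaining slots of [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 10, seed = 1)
#' cfg
#' @export
simConfig <- function(nGenes = 50L, nDecoys = 0L, snpRate = 1 / 90,
                      hetProb = 0.7, readLen = 150L, insertMean = 300,
                      insertSd = 75, rnaDepth = 60, dnaDepth = c(5, 25),
                      qStart = 40, qEnd = 30, qJitter = 3, nRate = 5e-4,
                      errorRate = NA_real_, seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    exonCountMu = 2, exonCountSize = 1, exonCountMax = 24L,
    exonMeanLog = log(189), exonSdLog = sqrt(2 * log(288 / 189)),
    intronMeanLog = log(114), intronSdLog = sqrt(2 * log(235 / 114)),
    minExonLen = 10L, minIntronLen = 20L, minTranscriptLen = 200L,
    utrFrac = 0.1, spliceMotifs = TRUE, flankLen = 300L)
  for (nm in names(defaults)) if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  intSlots <- c("exonCountMax", "minExonLen", "minIntronLen",
                "minTranscriptLen", "flankLen")
  for (nm in intSlots) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimConfig",
    nGenes = as.integer(nGenes), nDecoys = as.integer(nDecoys),
    snpRate = snpRate, hetProb = hetProb, readLen = as.integer(readLen),
    insertMean = insertMean, insertSd = insertSd, rnaDepth = rnaDepth,
    dnaDepth = as.numeric(dnaDepth), qStart = qStart, qEnd = qEnd,
    qJitter = qJitter, nRate = nRate, errorRate = as.numeric(errorRate),
    seed = as.integer(seed)),
    args))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nDecoys, "decoys\n")
  cat("  snpRate 1/", round(1 / object@snpRate), ", hetProb ",
      object@hetProb, ", reads 2x", object@readLen, " bp\n", sep = "")
  cat("  seed", object@seed, "\n")
})

#' Simulated genome: scaffolds, gene models, transcripts and proteins
#'
#' Truth container produced by [generateGenome()]. One scaffold carries one
#' gene (exons + introns) with flanking sequence; spliced transcripts carry a
#' planted coding sequence whose translation forms the reference protein set
#' used by the Unigene construction.
#'
#' @slot scaffolds [Biostrings::DNAStringSet] of genomic scaffolds.
#' @slot exons [GenomicRanges::GRanges] of exons (gene_id, exon_rank, decoy).
#' @slot transcripts spliced transcripts, sense strand.
#' @slot proteins translations of the planted coding sequences.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SimGenome", slots = c(
  scaffolds = "DNAStringSet", exons = "GRanges",
  transcripts = "DNAStringSet", proteins = "AAStringSet",
  config = "SimConfig"))

setMethod("show", "SimGenome", function(object) {
  n <- length(object@transcripts)
  dec <- sum(vapply(split(S4Vectors::mcols(object@exons)$decoy,
                          S4Vectors::mcols(object@exons)$gene_id), any, logical(1)))
  cat("SimGenome:", n, "genes (", dec, "decoys ),",
      sum(Biostrings::width(object@scaffolds)), "bp of scaffold sequence\n")
})

#' @describeIn SimGenome-class scaffold sequences.
#' @param x a `SimGenome`.
#' @export
scaffolds <- function(x) x@scaffolds

#' @describeIn SimGenome-class exon model as a `GRanges`.
#' @export
geneModels <- function(x) x@exons

#' @describeIn SimGenome-class spliced transcripts.
#' @export
transcripts <- function(x) x@transcripts

#' @describeIn SimGenome-class planted protein set.
#' @export
proteins <- function(x) x@proteins

#' Clone panel with phased truth variants
#'
#' Produced by [generateClonePanel()]. Each clone carries two haplotypes per
#' scaffold; the alt-allele carriage of each haplotype is stored so that clone
#' haplotype sequences can be rebuilt exactly ([cloneHaplotypes()]), which is
#' also how read simulation and the truth-consistency checks work.
#'
#' @slot scaffolds reference (all-ref-allele) scaffolds, decoys excluded.
#' @slot truth `DataFrame` of segregating sites: seqid, pos (1-based), ref, alt.
#' @slot hap1,hap2 logical site x clone matrices: does the haplotype carry alt?
#' @slot clones clone identifiers; the first is the reference clone.
#' @slot referenceClone the Maillette-analogue clone used for RNA sequencing
#'   and the guided assembly.
#' @slot depths per-clone DNA fold-coverage.
#' @export
setClass("ClonePanel", slots = c(
  scaffolds = "DNAStringSet", truth = "DataFrame",
  hap1 = "matrix", hap2 = "matrix", clones = "character",
  referenceClone = "character", depths = "numeric"))

setValidity("ClonePanel", function(object) {
  msg <- character()
  n <- length(object@clones)
  if (n < 2) msg <- c(msg, "a panel needs >= 2 clones")
  if (!identical(dim(object@hap1), dim(object@hap2)))
    msg <- c(msg, "haplotype matrices must agree in shape")
  if (nrow(object@truth) != nrow(object@hap1))
    msg <- c(msg, "truth table and haplotype matrices must agree in sites")
  if (!(object@referenceClone %in% object@clones))
    msg <- c(msg, "referenceClone must be a panel clone")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClonePanel", function(object) {
  cat("ClonePanel:", length(object@clones), "clones,",
      nrow(object@truth), "segregating sites\n")
  cat("  reference clone:", object@referenceClone,
      "| depths:", paste(round(object@depths, 1), collapse = ", "), "\n")
})

#' @describeIn ClonePanel-class clone identifiers.
#' @param x a `ClonePanel`.
#' @export
cloneIds <- function(x) x@clones

#' @describeIn ClonePanel-class the designated reference clone.
#' @export
referenceClone <- function(x) x@referenceClone

#' @describeIn ClonePanel-class truth variant table (seqid, pos, ref, alt).
#' @export
truthVariants <- function(x) x@truth

#' Genotype matrix over clones and concordant SNP sites
#'
#' Integer codes: 0 hom-ref, 1 het (ref/alt), 2 hom-alt, 3 het with two alt
#' alleles, NA missing (site not callable in that clone). Site metadata holds
#' seqid, 1-based position, ref and comma-separated alt alleles.
#'
#' @slot geno integer site x clone matrix.
#' @slot sites `DataFrame` with one row per site.
#' @export
setClass("GenotypeMatrix", slots = c(geno = "matrix", sites = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@geno) != nrow(object@sites))
    msg <- c(msg, "geno and sites must have the same number of rows")
  ok <- object@geno %in% c(0L, 1L, 2L, 3L) | is.na(object@geno)
  if (!all(ok)) msg <- c(msg, "genotype codes must be 0..3 or NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeMatrix-class build one from a code matrix and site table.
#' @param geno integer site x clone matrix of codes.
#' @param sites `DataFrame`/data.frame with columns seqid, pos, ref, alt.
#' @export
genotypeMatrix <- function(geno, sites) {
  new("GenotypeMatrix", geno = as.matrix(geno), sites = DataFrame(sites))
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@geno), "sites x",
      ncol(object@geno), "clones;",
      sum(is.na(object@geno)), "missing genotypes\n")
})

#' @describeIn GenotypeMatrix-class the integer code matrix.
#' @param x a `GenotypeMatrix`.
#' @export
genotypes <- function(x) x@geno

#' @describeIn GenotypeMatrix-class site metadata with per-site MAF.
#' @export
siteInfo <- function(x) {
  si <- x@sites
  si$maf <- siteMaf(x)
  si
}

#' @describeIn GenotypeMatrix-class number of sites.
#' @export
nSites <- function(x) nrow(x@geno)

# Per-site minor allele frequency over non-missing genotypes: allele counts
# are accumulated over the full allele set (ref + alts); MAF = 1 - max freq
# for biallelic sites this is min(p, 1 - p) and always lies in [0, 0.5].
siteMaf <- function(x) {
  g <- x@geno
  vapply(seq_len(nrow(g)), function(i) {
    cnt <- alleleCountsAtSite(g[i, ])
    tot <- sum(cnt)
    if (tot == 0) return(NA_real_)
    1 - max(cnt) / tot
  }, numeric(1))
}

# allele counts c(ref, alt1, alt2) from genotype codes of one site
alleleCountsAtSite <- function(codes) {
  codes <- codes[!is.na(codes)]
  c(ref  = 2 * sum(codes == 0L) + sum(codes == 1L),
    alt1 = sum(codes == 1L) + 2 * sum(codes == 2L) + sum(codes == 3L),
    alt2 = sum(codes == 3L))
}
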