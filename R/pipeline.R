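#' Default pipeline configuration
#'
#' Nested list of every stage's parameters, round-trippable through YAML
#' ([writePipelineConfig()] / [readPipelineConfig()]). The defaults form the
#' desk-scale demonstration run: 50 genes, 6 clones, the quoted thresholds
#' of every stage (trim limit 0.001 / min length 70, assembly k 25 and 63,
#' translated-search e-value 1e-20 with coverage 70 / identity 30, guided
#' iteration at similarities 0.95 then 0.98 with k 25..100 step 5 and at
#' most 8 iterations, callers at depth 5..50 / count 2 / frequency 40\% /
#' qualities 25 and 30, 1000 bootstraps).
#'
#' @param nGenes,nClones,seed convenience overrides of the commonest knobs.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(nGenes = 50L, nClones = 6L, seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(nGenes = as.integer(nGenes), nDecoys = 2L, nClones =
                 as.integer(nClones), snpRate = 1 / 90, hetProb = 0.7,
               readLen = 150L, insertMean = 300, insertSd = 75,
               rnaDepth = 60, dnaDepth = c(5, 25), qStart = 40, qEnd = 30,
               qJitter = 3, nRate = 5e-4),
    trim = list(limit = 0.001, minLen = 70L,
                adapters = "AGATCGGAAGAGC"),
    assembly = list(kValues = c(25L, 63L), minCount = 2L, minLen = 200L),
    unigene = list(evalueMax = 1e-20, minCov = 70, minIdent = 30),
    genespace = list(maxIter = 8L, sim1 = 0.95, simN = 0.98, kmin = 25L,
                     kmax = 100L, kstep = 5L, evalueMax = 1e-6),
    variants = list(minCov = 5L, maxCov = 50L, minCount = 2L, minFreq = 0.4,
                    minqA = 25L, flank = 5L, minqB = 30L, stringent = TRUE),
    popgen = list(bootstraps = 1000L))
}

#' @rdname pipelineConfig
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- function(x) if (is.list(x)) lapply(x, num) else x
  num(cfg)
}

# pre-flight validation: every threshold within its documented range; errors
# here abort before anything is written
validatePipelineConfig <- function(config) {
  need <- c("seed", "sim", "trim", "assembly", "unigene", "genespace",
            "variants", "popgen")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing block(s): ", paste(miss, collapse = ", "))
  with(config, {
    stopifnot(sim$nGenes >= 1, sim$nClones >= 2,
              trim$limit > 0, trim$limit < 1, trim$minLen >= 1,
              all(unlist(assembly$kValues) >= 15),
              all(unlist(assembly$kValues) <= 101),
              unigene$minCov > 0, unigene$minCov <= 100,
              unigene$minIdent > 0, unigene$minIdent <= 100,
              genespace$maxIter >= 1, genespace$sim1 > 0, genespace$sim1 <= 1,
              genespace$simN > 0, genespace$simN <= 1,
              genespace$kmin <= genespace$kmax,
              variants$minCov >= 1, variants$maxCov >= variants$minCov,
              variants$minFreq > 0, variants$minFreq <= 1,
              popgen$bootstraps >= 1)
  })
  invisible(TRUE)
}

stageLog <- function(dir, stage, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ",
                paste0(..., collapse = ""))
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

stageDone <- function(dir, stage) file.exists(file.path(dir, stage, ".done"))

markDone <- function(dir, stage) {
  writeLines(format(Sys.time()), file.path(dir, stage, ".done"))
}

#' Run the full pipeline
#'
#' simulate -> trim -> assemble -> unigene -> genespace -> structure ->
#' call/concord -> popgen, with plain-file handoff between stages (FASTA /
#' FASTQ / VCF / TSV under one subdirectory per stage), a per-stage log that
#' echoes the parameters used, an md5 manifest over every output file, and
#' per-stage resume: stages whose `.done` marker exists are skipped when
#' `resume = TRUE`.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir run directory (created).
#' @param resume skip completed stages.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, resume = FALSE) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (st in c("sim", "trim", "assembly", "unigene", "genespace",
               "structure", "variants", "popgen"))
    dir.create(file.path(outDir, st), showWarnings = FALSE)
  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  sd <- function(st) file.path(outDir, st)

  ## --- simulate -----------------------------------------------------------
  if (!(resume && stageDone(outDir, "sim"))) {
    sc <- config$sim
    cfg <- simConfig(nGenes = sc$nGenes, nDecoys = sc$nDecoys,
                     snpRate = sc$snpRate, hetProb = sc$hetProb,
                     readLen = sc$readLen, insertMean = sc$insertMean,
                     insertSd = sc$insertSd, rnaDepth = sc$rnaDepth,
                     dnaDepth = unlist(sc$dnaDepth), qStart = sc$qStart,
                     qEnd = sc$qEnd, qJitter = sc$qJitter, nRate = sc$nRate,
                     seed = config$seed)
    stageLog(outDir, "sim", "genes=", cfg@nGenes, " decoys=", cfg@nDecoys,
             " clones=", sc$nClones, " snpRate=", signif(cfg@snpRate, 3),
             " seed=", cfg@seed)
    genome <- generateGenome(cfg)
    panel <- generateClonePanel(genome, cfg, sc$nClones)
    writeXStringSet(genome@scaffolds, file.path(sd("sim"), "scaffolds.fasta"))
    writeXStringSet(genome@transcripts,
                    file.path(sd("sim"), "transcripts.fasta"))
    writeXStringSet(genome@proteins, file.path(sd("sim"), "proteins.fasta"))
    exportGeneModels(genome, file.path(sd("sim"), "genes.gff3"))
    writeTruthVcf(panel, file.path(sd("sim"), "truth.vcf"))
    utils::write.table(
      data.frame(clone = panel@clones, depth = panel@depths,
                 reference = panel@clones == panel@referenceClone),
      file.path(sd("sim"), "clones.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    rna <- simulateRnaReads(panel, genome, cfg)
    writeFastqPair(rna, file.path(sd("sim"), "rna"))
    dna <- simulateDnaReads(panel, cfg)
    for (cl in names(dna))
      writeFastqPair(dna[[cl]], file.path(sd("sim"), paste0("dna_", cl)))
    saveRefScaffolds <- panel@scaffolds
    writeXStringSet(saveRefScaffolds,
                    file.path(sd("sim"), "panel_reference.fasta"))
    markDone(outDir, "sim")
  }
  clones <- utils::read.table(file.path(sd("sim"), "clones.tsv"),
                              header = TRUE, sep = "\t")
  refClone <- clones$clone[clones$reference][1]

  ## --- trim ---------------------------------------------------------------
  if (!(resume && stageDone(outDir, "trim"))) {
    tc <- do.call(trimConfig, config$trim)
    stageLog(outDir, "trim", "limit=", tc$limit, " minLen=", tc$minLen,
             " adapters=", length(tc$adapters))
    rna <- readFastqPair(file.path(sd("sim"), "rna_1.fastq"),
                         file.path(sd("sim"), "rna_2.fastq"))
    tr <- trimPairs(rna, tc)
    writeFastqPair(tr$paired, file.path(sd("trim"), "rna"))
    writeQualityScaledXStringSet(tr$orphans,
                                 file.path(sd("trim"), "rna_orphans.fastq"))
    rep <- data.frame(set = "rna", as.data.frame(tr$report))
    for (cl in clones$clone) {
      p <- readFastqPair(file.path(sd("sim"), paste0("dna_", cl, "_1.fastq")),
                         file.path(sd("sim"), paste0("dna_", cl, "_2.fastq")))
      td <- trimPairs(p, tc)
      writeFastqPair(td$paired, file.path(sd("trim"), paste0("dna_", cl)))
      rep <- rbind(rep, data.frame(set = cl, as.data.frame(td$report)))
    }
    utils::write.table(rep, file.path(sd("trim"), "trim_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    markDone(outDir, "trim")
  }

  ## --- assemble -----------------------------------------------------------
  if (!(resume && stageDone(outDir, "assembly"))) {
    ac <- config$assembly
    rna <- readFastqPair(file.path(sd("trim"), "rna_1.fastq"),
                         file.path(sd("trim"), "rna_2.fastq"))
    metricsAll <- NULL
    for (k in unlist(ac$kValues)) {
      stageLog(outDir, "assembly", "k=", k, " minCount=", ac$minCount,
               " minLen=", ac$minLen)
      ctg <- assembleReads(rna$r1, rna$r2, k = k, minCount = ac$minCount,
                           minLen = ac$minLen)
      ev <- evaluateAssembly(ctg, rna)
      keep <- ctg[ev$supported]
      writeXStringSet(keep, file.path(sd("assembly"),
                                      sprintf("contigs_k%d.fasta", k)))
      met <- cbind(k = k, assemblyMetrics(keep), ev$metrics)
      metricsAll <- rbind(metricsAll, met)
    }
    utils::write.table(metricsAll,
                       file.path(sd("assembly"), "assembly_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    markDone(outDir, "assembly")
  }

  ## --- unigene ------------------------------------------------------------
  if (!(resume && stageDone(outDir, "unigene"))) {
    uc <- config$unigene
    prot <- readAAStringSet(file.path(sd("sim"), "proteins.fasta"))
    hitSets <- list(); contigSets <- list()
    for (k in unlist(config$assembly$kValues)) {
      lab <- paste0("k", k)
      ctg <- readDNAStringSet(file.path(sd("assembly"),
                                        sprintf("contigs_k%d.fasta", k)))
      contigSets[[lab]] <- ctg
      hitSets[[lab]] <- translatedSearch(ctg, prot, uc$evalueMax)
    }
    stageLog(outDir, "unigene", "evalueMax=", uc$evalueMax, " minCov=",
             uc$minCov, " minIdent=", uc$minIdent)
    uni <- buildUnigene(hitSets, contigSets, uc$minCov, uc$minIdent)
    writeXStringSet(uni, file.path(sd("unigene"), "unigene.fasta"))
    prov <- cbind(unigene_id = names(uni),
                  as.data.frame(S4Vectors::mcols(uni)))
    utils::write.table(prov, file.path(sd("unigene"), "unigene.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    markDone(outDir, "unigene")
  }

  ## --- genespace ----------------------------------------------------------
  if (!(resume && stageDone(outDir, "genespace"))) {
    gc <- config$genespace
    uni <- readDNAStringSet(file.path(sd("unigene"), "unigene.fasta"))
    dnaRef <- readFastqPair(
      file.path(sd("trim"), paste0("dna_", refClone, "_1.fastq")),
      file.path(sd("trim"), paste0("dna_", refClone, "_2.fastq")))
    stageLog(outDir, "genespace", "maxIter=", gc$maxIter, " sim1=", gc$sim1,
             " simN=", gc$simN, " k=", gc$kmin, "..", gc$kmax,
             " step ", gc$kstep)
    states <- iterateGenespace(uni, dnaRef, maxIter = gc$maxIter,
                               sim1 = gc$sim1, simN = gc$simN,
                               kmin = gc$kmin, kmax = gc$kmax,
                               kstep = gc$kstep, evalueMax = gc$evalueMax)
    iterRep <- data.frame(
      iteration = vapply(states, `[[`, integer(1), "iteration"),
      rebuilt = vapply(states, `[[`, integer(1), "rebuiltCount"),
      recruitedReads = vapply(states, `[[`, integer(1), "recruitedReads"),
      nContigs = vapply(states, function(s) length(s$contigs), integer(1)))
    utils::write.table(iterRep, file.path(sd("genespace"), "iterations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (s in states)
      writeXStringSet(s$contigs, file.path(
        sd("genespace"), sprintf("iter_%d.fasta", s$iteration)))
    comp <- composeGenespace(uni, states[[length(states)]]$contigs,
                             gc$evalueMax)
    writeXStringSet(comp$genespace,
                    file.path(sd("genespace"), "genespace.fasta"))
    members <- cbind(genespace_id = names(comp$genespace),
                     as.data.frame(S4Vectors::mcols(comp$genespace)))
    utils::write.table(members, file.path(sd("genespace"), "membership.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(comp$report, file.path(sd("genespace"), "classes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stageLog(outDir, "genespace", "iterations=", length(states),
             " rebuilt=", iterRep$rebuilt[nrow(iterRep)], "/", length(uni))
    markDone(outDir, "genespace")
  }

  ## --- structure ----------------------------------------------------------
  if (!(resume && stageDone(outDir, "structure"))) {
    uni <- readDNAStringSet(file.path(sd("unigene"), "unigene.fasta"))
    gs <- readDNAStringSet(file.path(sd("genespace"), "genespace.fasta"))
    members <- utils::read.table(file.path(sd("genespace"), "membership.tsv"),
                                 header = TRUE, sep = "\t")
    structs <- list(); rows <- NULL
    for (i in seq_len(nrow(members))) {
      if (members$origin[i] != "dna_contig") next
      first <- strsplit(members$members[i], ",")[[1]][1]
      if (!first %in% names(uni)) next
      st <- suppressWarnings(inferStructure(uni[[first]],
                                            gs[[members$genespace_id[i]]]))
      structs[[length(structs) + 1L]] <- st
      rows <- rbind(rows, data.frame(
        genespace_id = members$genespace_id[i], unigene_id = first,
        nExons = st$nExons, nIntrons = st$nIntrons,
        meanIdentity = st$meanIdentity))
    }
    if (length(structs)) {
      utils::write.table(structureSummary(structs),
                         file.path(sd("structure"), "summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(rows, file.path(sd("structure"), "structures.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      stageLog(outDir, "structure", nrow(rows), " structures, mean exons ",
               round(mean(rows$nExons), 2))
    } else {
      stageLog(outDir, "structure", "no DNA-derived sequences to analyze")
    }
    markDone(outDir, "structure")
  }

  ## --- variants -----------------------------------------------------------
  if (!(resume && stageDone(outDir, "variants"))) {
    vc <- config$variants
    gs <- readDNAStringSet(file.path(sd("genespace"), "genespace.fasta"))
    stageLog(outDir, "variants", "cov=", vc$minCov, "..", vc$maxCov,
             " count>=", vc$minCount, " freq>=", vc$minFreq,
             " q=", vc$minqA, "/", vc$minqB,
             if (vc$stringent) " stringent" else " relaxed")
    concList <- list(); pileups <- list(); maps <- list()
    for (cl in clones$clone) {
      p <- readFastqPair(file.path(sd("trim"), paste0("dna_", cl, "_1.fastq")),
                         file.path(sd("trim"), paste0("dna_", cl, "_2.fastq")))
      mp <- mapClone(p, gs, stringent = isTRUE(vc$stringent),
                     insertMean = config$sim$insertMean,
                     insertSd = config$sim$insertSd)
      pu <- clonePileup(mp, p, gs, vc$minqA, vc$flank, vc$minqB)
      calls <- callClone(pu, vc$minCov, vc$maxCov, vc$minCount, vc$minFreq)
      concList[[cl]] <- concordantCalls(calls$callsA, calls$callsB)
      pileups[[cl]] <- pu
      maps[[cl]] <- mp
      stageLog(outDir, "variants", cl, ": A=", nrow(calls$callsA),
               " B=", nrow(calls$callsB), " concordant=",
               nrow(concList[[cl]]))
    }
    flagged <- flagUnmappedRefs(maps, gs)
    writeLines(flagged, file.path(sd("variants"), "flagged_refs.txt"))
    bm <- buildGenotypeMatrix(concList, pileups, vc$minCov, vc$maxCov)
    writeGenotypeVcf(bm$gm, file.path(sd("variants"), "concordant.vcf"),
                     bm$dp, bm$adAlt)
    utils::write.table(privateAlleles(bm$gm),
                       file.path(sd("variants"), "private_alleles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    het <- heterozygosityPerClone(bm$gm)
    utils::write.table(data.frame(clone = names(het), hetFraction = het),
                       file.path(sd("variants"), "heterozygosity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stageLog(outDir, "variants", "matrix ", nSites(bm$gm), " sites x ",
             ncol(genotypes(bm$gm)), " clones; flagged refs: ",
             length(flagged))
    markDone(outDir, "variants")
  }

  ## --- popgen -------------------------------------------------------------
  if (!(resume && stageDone(outDir, "popgen"))) {
    pc <- config$popgen
    gm <- readGenotypeVcf(file.path(sd("variants"), "concordant.vcf"))
    gmF <- filterNoMissing(gm)
    stageLog(outDir, "popgen", nSites(gmF), " no-missing sites; bootstraps=",
             pc$bootstraps)
    utils::write.table(mafSpectrum(gmF),
                       file.path(sd("popgen"), "maf_spectrum.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    d <- prevostiDist(gmF)
    utils::write.table(round(d, 6), file.path(sd("popgen"), "distances.tsv"),
                       sep = "\t", quote = FALSE)
    tree <- bootstrapSupport(gmF, nReps = pc$bootstraps, seed = config$seed)
    ape::write.tree(tree, file.path(sd("popgen"), "upgma.nwk"))
    pca <- pcaGenotypes(gmF)
    utils::write.table(
      cbind(clone = rownames(pca$coords), as.data.frame(pca$coords)),
      file.path(sd("popgen"), "pca.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    markDone(outDir, "popgen")
  }

  ## --- manifest -----------------------------------------------------------
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in%
                   c("MANIFEST.tsv", "pipeline.log", ".done")]
  manifest <- data.frame(
    file = substring(files, nchar(outDir) + 2L),
    md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(outDir, "MANIFEST.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
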