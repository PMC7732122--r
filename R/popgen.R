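#' Prevosti absolute genetic distance
#'
#' d(i, j) = 1/(2m) * sum over the m loci and their alleles of
#' |p_ia - p_ja|, where p are within-individual allele frequencies (0, 1/2
#' or 1 for a diploid). A single locus contributes 1 for opposite
#' homozygotes and 1/2 for hom vs het. Multi-allelic sites enter with their
#' full allele vectors.
#'
#' @param gm a [GenotypeMatrix-class] without missing genotypes
#'   (apply [filterNoMissing()] first).
#' @return symmetric numeric matrix with clone dimnames, zero diagonal.
#' @export
prevostiDist <- function(gm) {
  g <- genotypes(gm)
  if (any(is.na(g)))
    stop("missing genotypes present; run filterNoMissing() first")
  m <- nrow(g)
  if (m == 0) stop("no sites")
  # within-individual allele frequencies per code 0..3 (ref, alt1, alt2)
  pRef <- matrix(c(1, 0.5, 0, 0)[g + 1L], nrow(g), ncol(g))
  pA1 <- matrix(c(0, 0.5, 1, 0.5)[g + 1L], nrow(g), ncol(g))
  pA2 <- matrix(c(0, 0, 0, 0.5)[g + 1L], nrow(g), ncol(g))
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(pRef[, i] - pRef[, j]) + abs(pA1[, i] - pA1[, j]) +
              abs(pA2[, i] - pA2[, j])) / (2 * m)
    }
  }
  d
}

#' Keep only sites genotyped in every clone
#'
#' Rare alleles are deliberately retained: there is no MAF floor, and
#' monomorphic sites pass.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterNoMissing <- function(gm) {
  keep <- rowSums(is.na(genotypes(gm))) == 0L
  genotypeMatrix(genotypes(gm)[keep, , drop = FALSE],
                 gm@sites[keep, , drop = FALSE])
}

#' Minor-allele-frequency spectrum
#'
#' MAF per site over all clones (must be complete); fractions are reported
#' over polymorphic sites in the bins (0, 0.05], (0.05, 0.4], (0.4, 0.5].
#'
#' @param gm a complete [GenotypeMatrix-class].
#' @return data.frame: bin, count, fraction.
#' @export
mafSpectrum <- function(gm) {
  if (any(is.na(genotypes(gm))))
    stop("missing genotypes present; run filterNoMissing() first")
  maf <- siteMaf(gm)
  poly <- maf[maf > 0]
  bins <- cut(poly, breaks = c(0, 0.05, 0.4, 0.5),
              labels = c("(0,0.05]", "(0.05,0.4]", "(0.4,0.5]"))
  tab <- table(bins)
  data.frame(bin = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(poly))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node height is half the merge distance, so
#' the tree is ultrametric. Ids are ordered lexicographically before
#' clustering so that ties merge deterministically on the smallest id pair.
#'
#' @param d symmetric distance matrix (zero diagonal) or `dist`.
#' @return an [ape::phylo] rooted ultrametric tree.
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric")
  o <- order(rownames(d))
  d <- d[o, o, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for the UPGMA tree
#'
#' Loci are resampled with replacement `nReps` times; each replicate matrix
#' is run through Prevosti + UPGMA and the support of every internal node of
#' the original tree is the percentage of replicates containing that
#' bipartition. Sites are put in canonical (seqid, pos) order first so the
#' supports do not depend on input locus order.
#'
#' @param gm a complete [GenotypeMatrix-class].
#' @param nReps number of replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @return the original tree with `node.label` set to support percentages.
#' @export
bootstrapSupport <- function(gm, nReps = 1000L, seed = 1L) {
  if (nReps < 1) stop("nReps must be >= 1")
  g <- genotypes(gm)
  if (any(is.na(g))) stop("missing genotypes present; filter first")
  o <- order(gm@sites$seqid, gm@sites$pos)
  gm <- genotypeMatrix(g[o, , drop = FALSE], gm@sites[o, , drop = FALSE])
  tree <- upgmaTree(prevostiDist(gm))
  m <- nSites(gm)
  set.seed(seed)
  boots <- vector("list", nReps)
  for (b in seq_len(nReps)) {
    idx <- sample.int(m, m, replace = TRUE)
    bm <- genotypeMatrix(genotypes(gm)[idx, , drop = FALSE],
                         gm@sites[idx, , drop = FALSE])
    boots[[b]] <- upgmaTree(prevostiDist(bm))
  }
  cnt <- ape::prop.clades(tree, boots, rooted = TRUE)
  cnt[is.na(cnt)] <- 0L
  tree$node.label <- round(100 * cnt / nReps, 1)
  tree
}

#' Principal component analysis of genotype dosages
#'
#' Genotypes are encoded as alt-allele dosage (0, 1, 2; the rare second-alt
#' heterozygote counts 1 dose of the primary alt), columns are mean-centered
#' without variance scaling, and the clone covariance is
#' eigen-decomposed via `prcomp`.
#'
#' @param gm a complete [GenotypeMatrix-class] with >= 3 clones.
#' @return list: `coords` (clones x PCs), `percentVar` per axis.
#' @export
pcaGenotypes <- function(gm) {
  g <- genotypes(gm)
  if (any(is.na(g))) stop("missing genotypes present; filter first")
  if (ncol(g) < 3) stop("PCA needs at least 3 clones")
  dosage <- matrix(c(0, 1, 2, 1)[g + 1L], nrow(g), ncol(g))
  X <- t(dosage)
  rownames(X) <- colnames(g)
  if (all(apply(X, 2, stats::var) == 0))
    stop("genotype matrix has zero variance; PCA is undefined")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(coords = p$x, percentVar = 100 * p$sdev^2 / sum(p$sdev^2))
}

#' Write / read a multi-sample genotype VCF
#'
#' VCF v4.2 with GT, DP and AD per sample; positions are 1-based as the
#' format requires. `readGenotypeVcf()` restores the
#' [GenotypeMatrix-class] exactly (GT only).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path file path.
#' @param dp,adAlt optional depth / alt-count matrices from
#'   [buildGenotypeMatrix()].
#' @return the path (write) or a [GenotypeMatrix-class] (read).
#' @export
writeGenotypeVcf <- function(gm, path, dp = NULL, adAlt = NULL) {
  g <- genotypes(gm)
  si <- gm@sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=orphangene",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
  gtStr <- c("0/0", "0/1", "1/1", "1/2")
  for (i in seq_len(nrow(g))) {
    fields <- vapply(seq_len(ncol(g)), function(j) {
      gt <- if (is.na(g[i, j])) "./." else gtStr[g[i, j] + 1L]
      d <- if (is.null(dp)) "." else dp[i, j]
      a <- if (is.null(adAlt)) "." else
        paste(max(0L, (if (is.null(dp)) 0L else dp[i, j]) - adAlt[i, j]),
              adAlt[i, j], sep = ",")
      paste(gt, d, a, sep = ":")
    }, character(1))
    writeLines(paste(c(si$seqid[i], si$pos[i], ".", si$ref[i], si$alt[i],
                       ".", "PASS", ".", "GT:DP:AD", fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeGenotypeVcf
#' @export
readGenotypeVcf <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#CHROM")]
  cols <- strsplit(hdr, "\t")[[1]]
  clones <- cols[-(1:9)]
  body <- ln[!startsWith(ln, "#")]
  if (length(body) == 0)
    return(genotypeMatrix(matrix(integer(0), 0, length(clones),
                                 dimnames = list(NULL, clones)),
                          DataFrame(seqid = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0))))
  f <- strsplit(body, "\t")
  seqid <- vapply(f, `[`, character(1), 1)
  pos <- as.integer(vapply(f, `[`, character(1), 2))
  ref <- vapply(f, `[`, character(1), 4)
  alt <- vapply(f, `[`, character(1), 5)
  codeOf <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "1/2" = 3L, "2/1" = 3L)
  g <- matrix(NA_integer_, length(body), length(clones),
              dimnames = list(NULL, clones))
  for (j in seq_along(clones)) {
    gt <- sub(":.*$", "", vapply(f, `[`, character(1), 9 + j))
    g[, j] <- unname(codeOf[gt])
  }
  genotypeMatrix(g, DataFrame(seqid = seqid, pos = pos, ref = ref, alt = alt))
}
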