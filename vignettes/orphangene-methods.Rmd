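---
title: "Building a gene space and concordant SNP genotypes for an orphan species"
author: "orphangene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a gene space and concordant SNP genotypes for an orphan species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many cultivated perennials — true lavender is the motivating case — have no
assembled genome, yet breeding programs need thousands of mapped markers and
a way to measure genetic distance between clones. `orphangene` implements a
desk-scale version of a resource-building strategy that needs only short-read
sequencing:

1. **Trim** paired-end reads on quality, ambiguity, adapters and length.
2. **Assemble** the transcriptome de novo (de Bruijn graph) and
   evaluate each assembly by mapping its own reads back.
3. **Select a Unigene**: a non-redundant set of coding sequences, one per
   best-hit protein in a reference protein set.
4. **Rebuild full genes** ("Genespace") by iteratively mapping genomic reads
   to the Unigene, rescuing broken pairs, and re-assembling — each round
   walks further into introns and flanks.
5. **Infer exon/intron structure** of every rebuilt gene by chaining local
   alignments of its spliced form against its genomic form.
6. **Call SNPs per clone with two independent callers** and keep only calls
   concordant in position and genotype.
7. **Analyse the panel**: Prevosti distances, a bootstrapped UPGMA tree, a
   dosage PCA and the minor-allele-frequency spectrum.

A seeded simulator (`generateGenome()`, `generateClonePanel()`,
`simulateRnaReads()`, `simulateDnaReads()`) generates a diploid founder
genome, a heterozygous clone panel and reads with truth files, so the whole
chain is testable without any external data.

## The simulator and what it emulates

Gene architecture follows published summary statistics for the lavender gene
space: exon count per gene is a shifted negative binomial (`1 +
NB(size = 1, mu = 2)`, truncated at 24) with mean 3 and median 2; exon
lengths are rounded log-normals matched to mean 288 bp / median 189 bp;
intron lengths to mean 235 bp / median 114 bp with a 20 bp floor (reported
zero-length introns are treated as alignment artifacts, and the simulator
never generates them). Each gene sits on its own scaffold with 300 bp
flanks; its transcript carries a planted coding sequence (ATG, stop-free
codons, stop) between 10% UTRs, whose translation forms the reference
protein set used by the translated search. Introns optionally carry GT..AG
dinucleotides.

Variant structure: segregating sites are planted at 1 per 90 bp. Clonally
propagated outbreeders retain far more heterozygosity than Hardy–Weinberg
sampling would give (two thirds to four fifths of per-clone genotype calls
in the motivating panel are heterozygous), and no haplotype-pool model can
push expected heterozygosity above one half. The simulator therefore draws
each clone's genotype directly — heterozygous with probability
`hetProb = 0.7`, the remainder split between the homozygotes — and phases
the alleles onto two clone haplotypes. Heterozygosity is accordingly
measured among a clone's **non-reference** genotype calls, matching how a
per-clone caller reports (hom-ref is not a call).

Reads: 2 × 150 bp pairs; fragments of 300 ± 75 bp obtained by chopping
molecules end to end, so molecule termini are covered the way sonication
covers them; RNA libraries are TruSeq-stranded (read 2 sense, read 1
antisense, recorded in the headers); per-clone genomic depths spread over
5–25× with the reference clone at the maximum (it alone feeds the guided
assembly). Qualities decline linearly Phred 40 → 30 along the read with
Gaussian jitter (sd 3), and substitutions are drawn per base at
`10^(-Q/10)`; an explicit `errorRate` can override that for controlled
experiments. RNA depth defaults to 60× per transcript: with a stranded
protocol only read 1 feeds the assembly graph, and transcript 5′ ends are
reachable only through short first fragments, so depth well above the
genomic 5–25× is needed — as it is in real transcriptome sequencing.

What the simulator does **not** model: indels and structural variants,
paralogous gene families, alternative isoforms, expression-level variation,
sequencing-machine-specific error profiles, and reference bias from a
diverged outgroup. Passing tests therefore demonstrate correctness of the
algorithms under substitution-only divergence on single-copy genes; they do
not certify behaviour on repeat-rich or isoform-rich real data.

## Trimming

`trimReads()` clips 3′ adapters first (semi-global prefix match, minimum
overlap 5, ≤10% mismatches — the tool the method emulates documents only
"adapter trimming", so the common 3′ semi-global convention is used), then
keeps the maximal-scoring segment under the per-base score
`limit − p_err` with `limit = 0.001` (the modified Mott algorithm). In
practice this keeps segments whose average quality exceeds Q30. Ambiguous
bases score as errors of probability 1, so a kept segment can never span an
N — this implements both the "no N" rule and the "split at N, keep the best
clean segment" behaviour in one objective. Ties between equal-scoring
segments go to the smallest start, then the smallest end, for determinism.
Reads shorter than 70 bp after trimming are discarded; `trimPairs()` keeps
surviving pairs together and routes single survivors to an orphan file.

## Transcript assembly

`assembleReads()` builds the graph from **read-1** k-mers only
(canonicalised), prunes k-mers seen fewer than `minCount = 2` times and
dead-end tips shorter than 2k, and uses read 2 for bubble resolution: a
branch is supported when at least one read-2 spells it end to end (all its
k-mers occur in the read-2 set). Among supported branches the higher mean
coverage wins, with lexicographic tie-breaks; a bubble with no supported
branch keeps both branches as separate contigs. Two further choices were
forced by heterozygous data:

* **Branch length cap.** A single heterozygous site makes a bubble of about
  2k nodes, but sites closer than k chain into one longer branch; the cap
  is therefore `3k + 200` bp of branch sequence rather than the bare 2k
  node count a single SNP would need.
* **Superbubbles.** Guided iterations re-inject previous contigs, which are
  haplotype mosaics; between two shared bridges the graph can hold three or
  more parallel equal-length paths that no two-branch rule resolves. Because
  variation is substitution-only, parallel paths have equal length, and a
  layered frontier walk from each fork finds the reconvergence node; the
  maximum-coverage path is kept. Trusted (guide) k-mers are exempt from
  coverage pruning but deliberately *not* from bubble or superbubble
  removal — protecting them makes bubbles accumulate across iterations.

Contigs shorter than 200 bp are dropped (matching the shortest contigs the
downstream selection admits). `assemblyMetrics()` reports N50 by the
cumulative-length definition, and `evaluateAssembly()` maps the assembly's
own pairs back: a pair is *good* when both mates align full-length on the
same contig in proper orientation. Contigs with good-pair coverage of at
least 1 over at least 90% of their bases are retained — a deliberate,
simple stand-in for composite read-support scores, which are out of scope.

The pipeline runs the single-k assembler at k = 25 and k = 63 and feeds
both assemblies to the Unigene merge, preserving the two-assembler
redundancy logic of the original protocol without a second assembler
implementation.

## Unigene selection

`translatedSearch()` aligns all six frames of each contig locally
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1 via Biostrings) against
candidate proteins sharing a 5-residue word, and converts scores to
e-values with gapped Karlin–Altschul constants (λ = 0.267, K = 0.041, the
published defaults for this matrix) over a search space of frame length ×
database residues. At desk scale this full dynamic programming is exact;
e-values on small databases are approximate by nature, which is why the
cutoff (`1e-20`) is also expressible as a bit score. Coverage is measured
**on the protein**. `buildUnigene()` keeps hits with coverage > 70% and
identity > 30%, selects per assembly the longest contig per best-hit
protein, and across assemblies the longest form with ties broken by higher
identity (the tie-break below e-value — bit score, then lexicographic
protein id — is a repository convention; the original protocol does not
state one). The result carries one record per protein.

## Iterative guided assembly ("Genespace")

`iterateGenespace()` maps the reference clone's genomic pairs to the
Unigene at (length fraction 1.0, similarity 0.95) in iteration 1 — the
lenient setting that tolerates exon/intron junction mates — and to the
previous iteration's contigs at 0.98 afterwards. Reads mapping equally well
at several positions are non-specific and excluded. Both mates of intact
*and broken* pairs are recruited: the unmapped mate of a broken pair is
precisely what reaches into introns. Recruited reads go through a multi-k
guided assembly (k = 25…100 step 5) in which the previous contigs are
trusted pseudo-reads, so earlier information is never lost. Iteration 1
runs unguided: injecting the Unigene itself would plant exon–exon junction
k-mers that do not exist in the genome and could produce spliced chimeras.

A Unigene sequence counts as **rebuilt** when one contig's maximal
collinear HSP chain (nucleotide alignment at e-value ≤ 1e-6) covers at
least 90% of it. The 90% single-contig rule matters: any exonic fragment
already matches its Unigene at iteration 1, so a mere match count would
saturate immediately and the no-increase stopping rule would end the run
before introns are bridged. Iterations stop when the rebuilt count fails to
increase, or at `maxIter = 8`.

`composeGenespace()` emits every Unigene sequence in its longest form: the
best-matching final contig when that is longer (origin `dna_contig`),
otherwise the RNA form verbatim — sequences missing from the DNA assembly
are never lost. A contig claimed by several Unigene sequences is emitted
once with all member ids (the concatenated case), and the report classifies
each Unigene sequence as longer / concatenated / shorter / unmatched.

## Exon/intron structure

`inferStructure()` chains local HSPs (shared-13-mer diagonal runs scored
+2/−3, ungapped Karlin–Altschul e-values with λ solved numerically and
K = 0.41) into the maximal-scoring collinear chain by dynamic programming;
overlapping neighbours are trimmed at the overlap midpoint, shifting query
and subject coordinates together so each HSP stays on its diagonal. Chained
subject intervals are exons. A subject gap is an intron when the query-side
gap is at most 10 bp (the tolerance that separates introns from alignment
slippage; no published value exists, and 10 bp is small against the 20 bp
minimum intron). Larger query gaps mean unassembled transcript sequence and
are reported separately (`otherLen`), so exons + introns + flanks + other
always partition the genomic sequence exactly. Flanks are subject sequence
outside the terminal exons, reported in subject orientation.

## Dual-caller SNP discovery

Per clone, `mapClone()` maps at (0.95, 0.90) — or (0.90, 0.80) for a
divergent taxon — and `clonePileup()` accumulates two filtered views:

* **Caller A** (frequency caller): bases from intact, specific pairs with
  base quality ≥ 25 *and* a 5-base flanking window ≥ 25. A site is callable
  at filtered depth 5–50; an allele passes with count ≥ 2 and ≥ 40% of site
  coverage; two passing alleles give the genotype, a single passing
  non-reference allele gives hom-alt.
* **Caller B** (likelihood caller): bases with quality ≥ 30 from intact and
  broken pairs; the maximum-likelihood diploid genotype over (ref, top alt)
  under `P(b|g) = 1−e`, `e/3`, or `(1−e)/2 + e/6` with a flat prior, then
  the same depth/count/frequency post-filters as caller A (the original
  protocol applies "similar filters" to its second caller).

`concordantCalls()` keeps a call only when both callers agree on position,
reference allele and unordered genotype. `buildGenotypeMatrix()` takes the
site union over clones; a clone without a call is hom-ref when its
caller-A-filtered depth is in the callable window and missing otherwise —
the published protocol never states this rule, but some rule is required to
define "no missing genotype data", and callable depth is the natural one.
Coordinates are 0-based half-open internally and 1-based in VCF output.
The maximum-coverage cutoff of 50 applies identically in both callers.
Genespace sequences that attract no read in any clone mapping are flagged
as candidate contaminants and can be purged from the Unigene.

## Genetic distances

Prevosti distance is `d(i,j) = 1/(2m) * Σ_loci Σ_alleles |p_i − p_j|` with
within-individual allele frequencies 0, ½, 1; opposite homozygotes at one
locus contribute 1 and hom-vs-het ½. Multi-allelic sites enter with full
allele vectors. Sites with any missing genotype are removed first
(`filterNoMissing()`; rare alleles are deliberately retained — no MAF
floor). UPGMA uses average-linkage `hclust` with ids sorted
lexicographically so ties merge deterministically; node height is half the
merge distance, so trees are ultrametric. Bootstrap support resamples loci
with replacement (sites first put in canonical order, making supports
independent of input locus order), rebuilds Prevosti + UPGMA per replicate,
and reports the percentage of replicates containing each original
bipartition; 1000 replicates by default. PCA encodes genotypes as
alt-dosage 0/1/2 (a second-alt heterozygote counts one dose of the primary
alt — a documented simplification), mean-centers without variance scaling,
and reports percent variance per axis; whether the original analysis used
dosages or a distance PCoA is not documented, and dosage PCA is the choice
made here.

## Problem sizes and runtime

The shipped configurations are desk-scale by design: the demonstration
pipeline simulates 50 genes (~90 kb of gene space) for 6 clones and runs
end to end in a few minutes on one CPU; the SNP-recovery study uses ~100 kb
of gene space at 20× with 0.1% error; distribution checks of the
architecture laws draw 10,000 genes without building sequence. These sizes
give statistical headroom (3 standard errors on every distributional check)
while keeping every analysis reproducible in minutes.

## Known limitations

* The assembler is single-k per pass with simple/superbubble popping only;
  repeat and isoform structures beyond two or three parallel paths are not
  resolved and may fragment.
* The mapper is substitution-only (seeded diagonals with ungapped
  extension, identity = matches over the aligned span). This matches the
  simulator's scope — no indels — and the acceptance semantics of
  length-fraction × similarity; on real indel-bearing data a banded-DP
  extension would be required.
* E-values for the translated search use published Karlin–Altschul
  constants on small databases, so absolute values are approximate near the
  cutoff; thresholds may be set as bit scores where that matters.
* With a strictly stranded RNA protocol and a read-1-only graph, transcript
  5′ termini are systematically thin; the shortest transcripts may fail the
  70% protein-coverage rule and drop from the Unigene, which mirrors the
  length bias visible in the original selection.
* Heterozygosity is simulated per site, independently across sites and
  clones; linkage and shared ancestry are absent, so panel-level distances
  are larger and flatter than in a real, related clone collection.
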