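#' GenomeAnnotation: sequences plus ordered gene models
#'
#' The coordinate backbone for synteny, PAV calling and read coverage:
#' scaffold/chromosome sequences, gene models ordered by start coordinate
#' within each sequence, and one cDNA per gene (the coding strand).
#' Gene models carry their identifier both as names and in the
#' \code{gene_id} metadata column.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} of scaffolds.
#' @slot genes A \link[GenomicRanges]{GRanges} of gene spans (1-based,
#'   inclusive) with a \code{gene_id} metadata column.
#' @slot cdna A \link[Biostrings]{DNAStringSet}, one entry per gene,
#'   named by \code{gene_id}.
#'
#' @seealso [readGenome()], [simulateGenomePair()]
#' @export
setClass("GenomeAnnotation",
  representation(sequences = "DNAStringSet",
                 genes = "GRanges",
                 cdna = "DNAStringSet"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  ids <- object@genes$gene_id
  if (is.null(ids)) return("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate gene identifiers")
  seqn <- as.character(GenomeInfoDb::seqnames(object@genes))
  if (!all(seqn %in% names(object@sequences))) {
    msg <- c(msg, "gene on a sequence absent from 'sequences'")
  } else if (length(object@genes)) {
    lens <- Biostrings::width(object@sequences)[match(seqn, names(object@sequences))]
    if (any(GenomicRanges::end(object@genes) > lens) ||
        any(GenomicRanges::start(object@genes) < 1L)) {
      msg <- c(msg, "gene coordinates outside sequence bounds")
    }
  }
  if (length(object@cdna) && !setequal(names(object@cdna), ids)) {
    msg <- c(msg, "cdna names do not match gene identifiers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param sequences \link[Biostrings]{DNAStringSet} of scaffolds (named).
#' @param genes \link[GenomicRanges]{GRanges} with a \code{gene_id}
#'   metadata column; sorted by start within each sequence on construction.
#' @param cdna optional \link[Biostrings]{DNAStringSet} named by gene id;
#'   when missing, cDNAs are extracted from the gene spans (reverse
#'   complemented for minus-strand genes).
#' @return A \linkS4class{GenomeAnnotation}.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(s1 = "ATGGCCAAATTTGGGTAA"))
#' gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 18), strand = "+",
#'                              gene_id = "g1")
#' ga <- GenomeAnnotation(seqs, gr)
#' cdnaSeqs(ga)
#' @export
GenomeAnnotation <- function(sequences, genes, cdna = NULL) {
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  names(genes) <- genes$gene_id
  if (is.null(cdna)) {
    cdna <- extractCdna(sequences, genes)
  }
  methods::new("GenomeAnnotation", sequences = sequences, genes = genes,
               cdna = cdna)
}

#' Extract per-gene cDNA from genomic sequence
#'
#' Gene models here are single-exon (the simulator plants intronless
#' genes); the cDNA is the gene span on the coding strand.
#'
#' @param sequences DNAStringSet of scaffolds.
#' @param genes GRanges with \code{gene_id}.
#' @return DNAStringSet named by gene id.
#' @export
extractCdna <- function(sequences, genes) {
  if (length(genes) == 0L) {
    return(Biostrings::DNAStringSet())
  }
  seqn <- as.character(GenomeInfoDb::seqnames(genes))
  out <- Biostrings::DNAStringSet(lapply(seq_along(genes), function(i) {
    s <- Biostrings::subseq(sequences[[seqn[i]]],
                            GenomicRanges::start(genes)[i],
                            GenomicRanges::end(genes)[i])
    if (as.character(GenomicRanges::strand(genes)[i]) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    s
  }))
  names(out) <- genes$gene_id
  out
}

#' @describeIn GenomeAnnotation-class scaffold sequences
#' @param x a GenomeAnnotation.
#' @export
genomeSequences <- function(x) x@sequences

#' @describeIn GenomeAnnotation-class gene models as GRanges
#' @export
geneModels <- function(x) x@genes

#' @describeIn GenomeAnnotation-class per-gene cDNA
#' @export
cdnaSeqs <- function(x) x@cdna

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d sequence(s), %.3f Mb, %d gene(s)\n",
              length(object@sequences),
              sum(Biostrings::width(object@sequences)) / 1e6,
              length(object@genes)))
})

#' SimulationSpec: parameters of the two-genotype simulator
#'
#' Defines the study conditions emulated by the simulator: an ancestral
#' gene-bearing genome split into two genotypes (A, the wild-like donor;
#' B, the cultivated-like reference) with planted genotype-specific genes,
#' planted SNVs with optionally elevated pericentromeric density, LTR
#' pairs diverged to known ages, uniform-coverage substitution-error
#' reads, and negative-binomial tissue counts with planted
#' tissue-specific genes.
#'
#' @slot seed integer run seed; identical specs give byte-identical output.
#' @slot nScaffolds,scaffoldLength genome layout (bp).
#' @slot nGenes,geneLength,intergenicLength gene layout (bp); gene length
#'   must be a codon multiple.
#' @slot snvRate planted substitutions per site between the genotypes.
#' @slot periStart,periEnd,periMultiplier pericentromere-like interval
#'   (bp, applied on every scaffold) where SNV density is multiplied.
#' @slot nSpecificA,nSpecificB planted genotype-specific gene counts.
#' @slot specificMode "deletion" (whole-gene absence) or "partial"
#'   (locus retained but diverged beyond recognition).
#' @slot orthologKs extra synonymous divergence planted at fourfold
#'   degenerate sites of shared genes (substitutions per site; 0 = none).
#' @slot nLtrPairs,ltrAges,ltrLength,ltrRate LTR element simulation:
#'   ages in MYA (recycled over elements) and clock rate in
#'   substitutions per site per year.
#' @slot readLength,readDepth,readErrorRate single-end read simulation.
#' @slot tissues,repsPerTissue,nbDispersion,specificFractionExpr,foldChange
#'   tissue count matrix simulation (negative binomial).
#' @slot exprMeanLog,exprSdLog log-normal distribution of baseline gene
#'   means in the count simulator.
#' @slot randomStrand plant genes on random strands instead of forward.
#'
#' @seealso [simulationSpec()]
#' @export
setClass("SimulationSpec",
  representation(seed = "integer",
                 nScaffolds = "integer", scaffoldLength = "integer",
                 nGenes = "integer", geneLength = "integer",
                 intergenicLength = "integer",
                 snvRate = "numeric",
                 periStart = "numeric", periEnd = "numeric",
                 periMultiplier = "numeric",
                 nSpecificA = "integer", nSpecificB = "integer",
                 specificMode = "character",
                 orthologKs = "numeric",
                 nLtrPairs = "integer", ltrAges = "numeric",
                 ltrLength = "integer", ltrRate = "numeric",
                 readLength = "integer", readDepth = "numeric",
                 readErrorRate = "numeric",
                 tissues = "character", repsPerTissue = "integer",
                 nbDispersion = "numeric",
                 specificFractionExpr = "numeric", foldChange = "numeric",
                 exprMeanLog = "numeric", exprSdLog = "numeric",
                 randomStrand = "logical"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  for (sl in c("nScaffolds", "scaffoldLength", "nGenes", "geneLength",
               "intergenicLength", "readLength", "ltrLength")) {
    if (methods::slot(object, sl) <= 0L) {
      msg <- c(msg, sprintf("'%s' must be positive", sl))
    }
  }
  if (object@geneLength %% 3L != 0L) {
    msg <- c(msg, "'geneLength' must be a multiple of 3")
  }
  if (object@snvRate < 0 || object@snvRate > 0.2) {
    msg <- c(msg, "'snvRate' must be in [0, 0.2]")
  }
  if (object@periMultiplier < 1) msg <- c(msg, "'periMultiplier' must be >= 1")
  if (object@snvRate * object@periMultiplier > 1) {
    msg <- c(msg, "pericentromeric SNV rate exceeds 1")
  }
  if (object@periEnd < object@periStart) {
    msg <- c(msg, "'periEnd' must be >= 'periStart'")
  }
  if (object@nSpecificA < 0L || object@nSpecificB < 0L) {
    msg <- c(msg, "specific gene counts must be non-negative")
  }
  if (!object@specificMode %in% c("deletion", "partial")) {
    msg <- c(msg, "'specificMode' must be 'deletion' or 'partial'")
  }
  if (any(object@ltrAges < 0)) msg <- c(msg, "'ltrAges' must be non-negative")
  if (object@ltrRate <= 0) msg <- c(msg, "'ltrRate' must be positive")
  if (object@readDepth <= 0) msg <- c(msg, "'readDepth' must be positive")
  if (object@readErrorRate < 0 || object@readErrorRate > 0.5) {
    msg <- c(msg, "'readErrorRate' must be in [0, 0.5]")
  }
  if (object@nbDispersion <= 0) msg <- c(msg, "'nbDispersion' must be > 0")
  if (object@foldChange < 1) msg <- c(msg, "'foldChange' must be >= 1")
  if (object@specificFractionExpr < 0 || object@specificFractionExpr > 1) {
    msg <- c(msg, "'specificFractionExpr' must be a proportion")
  }
  if (length(msg)) msg else TRUE
})

#' Build a SimulationSpec with study-condition defaults
#'
#' Defaults mirror the emulated study design at desk scale: two inbred
#' genotypes, a pericentromere-like interval with threefold SNV density,
#' whole-gene presence/absence, a 1.3e-8 per-site-per-year LTR clock,
#' uniform 10x single-end reads, and six tissues with two biological
#' replicates each.
#'
#' @param seed integer run seed.
#' @param nScaffolds,scaffoldLength,nGenes,geneLength,intergenicLength
#'   genome layout.
#' @param snvRate planted per-site substitution rate between genotypes.
#' @param periStart,periEnd,periMultiplier pericentromere-like interval
#'   and its density multiplier.
#' @param nSpecificA,nSpecificB planted genotype-specific gene counts.
#' @param specificMode "deletion" or "partial".
#' @param orthologKs extra synonymous divergence at fourfold sites.
#' @param nLtrPairs,ltrAges,ltrLength,ltrRate LTR pair simulation.
#' @param readLength,readDepth,readErrorRate read simulation.
#' @param tissues,repsPerTissue,nbDispersion,specificFractionExpr,foldChange
#'   count matrix simulation.
#' @param exprMeanLog,exprSdLog baseline expression log-normal parameters.
#' @param randomStrand plant genes on random strands.
#' @return A validated \linkS4class{SimulationSpec}.
#' @examples
#' spec <- simulationSpec(seed = 1, nGenes = 20, nScaffolds = 1,
#'                        scaffoldLength = 60000L)
#' spec
#' @export
simulationSpec <- function(seed = 1L,
                           nScaffolds = 2L,
                           scaffoldLength = 200000L,
                           nGenes = 80L,
                           geneLength = 999L,
                           intergenicLength = 1200L,
                           snvRate = 0.002,
                           periStart = 60000,
                           periEnd = 140000,
                           periMultiplier = 3,
                           nSpecificA = 5L,
                           nSpecificB = 5L,
                           specificMode = "deletion",
                           orthologKs = 0,
                           nLtrPairs = 20L,
                           ltrAges = c(0.5, 1, 1.5, 2),
                           ltrLength = 10000L,
                           ltrRate = 1.3e-8,
                           readLength = 100L,
                           readDepth = 10,
                           readErrorRate = 0,
                           tissues = c("root", "seedling", "leaf", "stem",
                                       "kernel", "spikelet"),
                           repsPerTissue = 2L,
                           nbDispersion = 0.05,
                           specificFractionExpr = 0.05,
                           foldChange = 4,
                           exprMeanLog = log(1000),
                           exprSdLog = 0.5,
                           randomStrand = FALSE) {
  methods::new("SimulationSpec",
    seed = as.integer(seed), nScaffolds = as.integer(nScaffolds),
    scaffoldLength = as.integer(scaffoldLength), nGenes = as.integer(nGenes),
    geneLength = as.integer(geneLength),
    intergenicLength = as.integer(intergenicLength),
    snvRate = snvRate, periStart = periStart, periEnd = periEnd,
    periMultiplier = periMultiplier,
    nSpecificA = as.integer(nSpecificA), nSpecificB = as.integer(nSpecificB),
    specificMode = specificMode, orthologKs = orthologKs,
    nLtrPairs = as.integer(nLtrPairs), ltrAges = ltrAges,
    ltrLength = as.integer(ltrLength), ltrRate = ltrRate,
    readLength = as.integer(readLength), readDepth = readDepth,
    readErrorRate = readErrorRate, tissues = tissues,
    repsPerTissue = as.integer(repsPerTissue), nbDispersion = nbDispersion,
    specificFractionExpr = specificFractionExpr, foldChange = foldChange,
    exprMeanLog = exprMeanLog, exprSdLog = exprSdLog,
    randomStrand = randomStrand)
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0(
    "SimulationSpec (seed %d): %d scaffold(s) x %d bp, %d genes\n",
    "  SNV rate %.4g (x%.3g in [%d, %d]); specific genes A=%d B=%d (%s)\n",
    "  LTR: %d pairs, ages {%s} MYA, rate %.3g; reads: %dbp %sx err %.3g\n",
    "  expression: %d tissues x %d reps, dispersion %.3g, fold %.3g\n"),
    object@seed, object@nScaffolds, object@scaffoldLength, object@nGenes,
    object@snvRate, object@periMultiplier, as.integer(object@periStart),
    as.integer(object@periEnd), object@nSpecificA, object@nSpecificB,
    object@specificMode, object@nLtrPairs,
    paste(object@ltrAges, collapse = ","), object@ltrRate,
    object@readLength, format(object@readDepth), object@readErrorRate,
    length(object@tissues), object@repsPerTissue, object@nbDispersion,
    object@foldChange))
})

#' GenomeTruth: recorded ground truth of a simulated genotype pair
#'
#' @slot specificA,specificB identifiers of the planted genotype-specific
#'   genes (present only in A, resp. only in B).
#' @slot snv data.frame of planted SNVs with positions in both genomes'
#'   coordinates (\code{scaffold}, \code{posA}, \code{posB}, \code{ref},
#'   \code{alt}; 1-based; ref is the A allele).
#' @slot orthologMap data.frame \code{geneA}, \code{geneB}, \code{ks}
#'   (planted extra synonymous divergence).
#' @slot ltrAges named numeric, element id to true age in MYA.
#' @slot tissueSpecific data.frame \code{gene}, \code{tissue}.
#' @export
setClass("GenomeTruth",
  representation(specificA = "character", specificB = "character",
                 snv = "data.frame", orthologMap = "data.frame",
                 ltrAges = "numeric", tissueSpecific = "data.frame"))

setMethod("show", "GenomeTruth", function(object) {
  cat(sprintf(paste0("GenomeTruth: %d A-specific, %d B-specific genes; ",
                     "%d SNVs; %d ortholog pairs; %d LTR ages; ",
                     "%d tissue-specific genes\n"),
              length(object@specificA), length(object@specificB),
              nrow(object@snv), nrow(object@orthologMap),
              length(object@ltrAges), nrow(object@tissueSpecific)))
})

#' @describeIn GenomeTruth-class planted A-specific gene ids
#' @param x a GenomeTruth.
#' @export
truthSpecificA <- function(x) x@specificA

#' @describeIn GenomeTruth-class planted B-specific gene ids
#' @export
truthSpecificB <- function(x) x@specificB

#' @describeIn GenomeTruth-class planted SNV table
#' @export
truthSnv <- function(x) x@snv

#' @describeIn GenomeTruth-class planted ortholog map
#' @export
truthOrthologs <- function(x) x@orthologMap

#' @describeIn GenomeTruth-class true LTR element ages (MYA)
#' @export
truthLtrAges <- function(x) x@ltrAges

#' @describeIn GenomeTruth-class planted tissue-specific genes
#' @export
truthTissueSpecific <- function(x) x@tissueSpecific
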