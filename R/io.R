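# Readers and writers for the standard interchange formats: FASTA and
# FASTQ via Biostrings, GFF3 via rtracklayer, minimal VCF and BEDGRAPH
# writers, TSV tables. GFF3 gene coordinates are 1-based inclusive;
# BEDGRAPH intervals are 0-based half-open.

#' Read a genome from FASTA + GFF3
#'
#' Loads scaffold sequences and \code{gene} features (with \code{ID}
#' attributes), validates identifiers and coordinate bounds, and orders
#' genes by start within each scaffold.
#'
#' @param fastaPath FASTA of scaffold sequences.
#' @param gffPath GFF3 with \code{gene} features carrying \code{ID=}.
#' @param cdnaPath optional FASTA of per-gene cDNA named by gene id;
#'   when absent, cDNAs are extracted from the (single-exon) gene spans.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
readGenome <- function(fastaPath, gffPath, cdnaPath = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gffPath)
  genes <- gff[gff$type == "gene"]
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("parse error in ", gffPath, ": gene feature without ID attribute",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("parse error in ", gffPath, ": duplicate gene ID '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  seqn <- as.character(GenomeInfoDb::seqnames(genes))
  if (!all(seqn %in% names(seqs))) {
    stop("parse error in ", gffPath, ": gene on unknown sequence '",
         setdiff(seqn, names(seqs))[1L], "'", call. = FALSE)
  }
  lens <- Biostrings::width(seqs)[match(seqn, names(seqs))]
  bad <- which(GenomicRanges::end(genes) > lens |
               GenomicRanges::start(genes) < 1L)
  if (length(bad)) {
    stop("parse error in ", gffPath, ": gene '", ids[bad[1L]],
         "' outside sequence bounds", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(seqn,
          IRanges::IRanges(GenomicRanges::start(genes),
                           GenomicRanges::end(genes)),
          strand = GenomicRanges::strand(genes), gene_id = ids)
  cdna <- if (!is.null(cdnaPath)) Biostrings::readDNAStringSet(cdnaPath) else NULL
  if (!is.null(cdna)) names(cdna) <- sub("\\s.*$", "", names(cdna))
  GenomeAnnotation(seqs, gr, cdna)
}

#' Write a genome as FASTA + GFF3 (+ optional cDNA FASTA)
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param fastaPath,gffPath,cdnaPath output paths (\code{cdnaPath} may
#'   be NULL).
#' @return Invisibly, the genome.
#' @export
writeGenome <- function(genome, fastaPath, gffPath, cdnaPath = NULL) {
  Biostrings::writeXStringSet(genomeSequences(genome), fastaPath)
  gr <- geneModels(genome)
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  out$source <- "wildcomp"
  out$type <- "gene"
  out$ID <- gr$gene_id
  rtracklayer::export(out, gffPath, format = "gff3")
  if (!is.null(cdnaPath)) {
    Biostrings::writeXStringSet(cdnaSeqs(genome), cdnaPath)
  }
  invisible(genome)
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads named \link[Biostrings]{DNAStringSet}.
#' @param path output FASTQ path.
#' @param qualityChar constant per-base quality character.
#' @return Invisibly, the path.
#' @export
writeFastqFile <- function(reads, path, qualityChar = "I") {
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    strrep(qualityChar, w), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ path.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
readFastqFile <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write SNVs as a minimal VCF
#'
#' Eight-column records with DP and AF in INFO; positions 1-based per
#' the VCF standard.
#'
#' @param snvs SNV \link[GenomicRanges]{GRanges} from [callSnvs()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSnvVcf <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                   "QUAL", "FILTER", "INFO"),
                                 collapse = "\t"))), con)
  if (length(snvs)) {
    writeLines(paste(as.character(GenomeInfoDb::seqnames(snvs)),
                     GenomicRanges::start(snvs), ".", snvs$ref, snvs$alt,
                     ".", "PASS",
                     sprintf("DP=%d;AF=%.4f", snvs$depth, snvs$altFraction),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write window densities as BEDGRAPH (0-based half-open)
#'
#' @param wd window \link[GenomicRanges]{GRanges} from [windowDensity()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeBedgraph <- function(wd, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(wd)),
                   start = GenomicRanges::start(wd) - 1L,
                   end = GenomicRanges::end(wd),
                   value = wd$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write/read a count matrix with its tissue sidecar
#'
#' The matrix TSV has a header of sample names and gene ids in the
#' first column; the sidecar TSV maps sample to tissue.
#'
#' @param counts genes x samples matrix.
#' @param tissueMap named character, sample to tissue.
#' @param countsPath,tissuePath output paths.
#' @return Invisibly, \code{countsPath}.
#' @export
writeCountsTsv <- function(counts, tissueMap, countsPath, tissuePath) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(tissueMap), tissue = tissueMap),
              tissuePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

#' @rdname writeCountsTsv
#' @return For \code{readCountsTsv}, a list with \code{counts} and
#'   \code{tissueMap}.
#' @export
readCountsTsv <- function(countsPath, tissuePath) {
  df <- read.table(countsPath, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df[[1L]]
  ts <- read.table(tissuePath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  list(counts = counts, tissueMap = stats::setNames(ts$tissue, ts$sample))
}
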