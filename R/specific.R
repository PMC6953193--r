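# Genotype-specific (presence/absence) gene classification, the
# three-step procedure: (1) a gene whose cDNA has no cross-genome
# placement at the identity/coverage gates is a candidate; (2)
# candidates found in syntenic blocks are excluded; (3) a candidate is
# confirmed high-confidence specific when reads of the OTHER genotype
# cover less than half of its span. Step 3 reads the published rule in
# its logically consistent direction (coverage by the other genotype's
# reads evidences presence there, so low coverage confirms absence);
# both the threshold and the direction are exposed.

.callLevels <- c("placed", "syntenic_excluded", "candidate",
                 "high_confidence_specific")

#' Candidate genotype-specific genes by failed cross-placement
#'
#' Aligns each gene's cDNA to the other genotype's genome; genes with at
#' least one placement passing the identity/coverage gates are
#' \code{placed}, the rest are \code{candidate} specific genes.
#'
#' @param cdnas named \link[Biostrings]{DNAStringSet} of the focal
#'   genotype's cDNAs.
#' @param genomeOther the other genotype's genome
#'   (\linkS4class{GenomeAnnotation} or DNAStringSet).
#' @param minIdentity,minCoverage placement gates (80\% / 50\%).
#' @param ... further arguments to [mapCdna()].
#' @return data.frame: \code{gene}, \code{status}, \code{bestIdentity},
#'   \code{bestCoverage} (NA when no alignment at all),
#'   \code{coveredFraction} (NA until [coverageConfirm()]).
#' @export
findCandidates <- function(cdnas, genomeOther, minIdentity = 0.80,
                           minCoverage = 0.50, ...) {
  mp <- mapCdna(cdnas, genomeOther, minIdentity = minIdentity,
                minCoverage = minCoverage, ...)
  pl <- mp$placements
  best <- pl[!duplicated(pl$query), , drop = FALSE]  # sorted best-first
  ids <- names(cdnas)
  m <- match(ids, best$query)
  data.frame(gene = ids,
             status = ifelse(ids %in% best$query, "placed", "candidate"),
             bestIdentity = best$identity[m],
             bestCoverage = best$coverage[m],
             coveredFraction = NA_real_,
             stringsAsFactors = FALSE)
}

#' Exclude syntenic genes from the candidate set
#'
#' Candidates whose gene lies in a syntenic block are reclassified
#' \code{syntenic_excluded}: a collinear gene is present in both
#' genomes.
#'
#' @param calls call table from [findCandidates()].
#' @param syntenicSet character vector of syntenic gene identifiers for
#'   this genotype (see [syntenicGeneSet()]).
#' @return The updated call table.
#' @export
excludeSyntenic <- function(calls, syntenicSet) {
  sel <- calls$status == "candidate" & calls$gene %in% syntenicSet
  calls$status[sel] <- "syntenic_excluded"
  calls
}

#' Confirm candidates by the other genotype's read coverage
#'
#' Maps the other genotype's reads onto the focal genome and computes,
#' per candidate gene, the fraction of its span covered at depth
#' \code{coveredMinDepth} or more. Candidates covered on less than
#' \code{maxCoveredFraction} of their span (strict) become
#' \code{high_confidence_specific}; the rest stay \code{candidate}.
#'
#' @param calls call table from [findCandidates()] /
#'   [excludeSyntenic()].
#' @param readsOther reads of the other genotype
#'   (\link[Biostrings]{DNAStringSet}), ignored when \code{placements}
#'   is supplied.
#' @param genome the focal genotype's \linkS4class{GenomeAnnotation}.
#' @param coveredMinDepth depth at which a base counts as covered.
#' @param maxCoveredFraction candidates strictly below this covered
#'   fraction are confirmed.
#' @param maxSubstitutions mismatch budget for the read mapping.
#' @param placements optional precomputed [mapReads()] table.
#' @return The updated call table with \code{coveredFraction} filled for
#'   all genes present in \code{genome}.
#' @export
coverageConfirm <- function(calls, readsOther, genome,
                            coveredMinDepth = 1L, maxCoveredFraction = 0.50,
                            maxSubstitutions = 2L, placements = NULL) {
  if (is.null(placements)) {
    placements <- mapReads(readsOther, genome,
                           maxSubstitutions = maxSubstitutions)
  }
  cv <- geneCoverage(placements, genome, minDepth = coveredMinDepth)
  m <- match(calls$gene, cv$gene)
  if (anyNA(m[calls$status == "candidate"])) {
    stop("consistency error: candidate gene absent from 'genome'",
         call. = FALSE)
  }
  calls$coveredFraction <- cv$coveredFraction[m]
  confirm <- calls$status == "candidate" &
    !is.na(calls$coveredFraction) &
    calls$coveredFraction < maxCoveredFraction
  calls$status[confirm] <- "high_confidence_specific"
  calls
}

#' Full genotype-specific gene classification for one direction
#'
#' Runs the three steps for genes of genotype \code{focal} against
#' genotype \code{other}: cross-placement of cDNAs, synteny exclusion,
#' read-coverage confirmation. Swapping the genotypes recovers the
#' other direction.
#'
#' @param genomeFocal,genomeOther \linkS4class{GenomeAnnotation}s.
#' @param readsOther reads of the other genotype mapped onto
#'   \code{genomeFocal}.
#' @param syntenicSet syntenic gene ids of the focal genotype (may be
#'   empty).
#' @param minIdentity,minCoverage,coveredMinDepth,maxCoveredFraction,maxSubstitutions
#'   stage thresholds, see the step functions.
#' @param placements optional precomputed read placements on
#'   \code{genomeFocal}.
#' @return The call table (one row per focal gene).
#' @export
callSpecificGenes <- function(genomeFocal, genomeOther, readsOther,
                              syntenicSet = character(0),
                              minIdentity = 0.80, minCoverage = 0.50,
                              coveredMinDepth = 1L,
                              maxCoveredFraction = 0.50,
                              maxSubstitutions = 2L, placements = NULL) {
  calls <- findCandidates(cdnaSeqs(genomeFocal), genomeOther,
                          minIdentity = minIdentity,
                          minCoverage = minCoverage)
  calls <- excludeSyntenic(calls, syntenicSet)
  coverageConfirm(calls, readsOther, genomeFocal,
                  coveredMinDepth = coveredMinDepth,
                  maxCoveredFraction = maxCoveredFraction,
                  maxSubstitutions = maxSubstitutions,
                  placements = placements)
}
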