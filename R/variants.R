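# Read mapping and SNV calling under the published rules: a read is
# placed at its minimum-mismatch locus if it has at most maxSubstitutions
# mismatches (ties at distinct loci are discarded as ambiguous); a site
# is an SNV iff pileup depth >= minDepth and the most frequent
# non-reference allele reaches minAltFraction (0.9 by default: both
# genotypes are inbred, so true variants are homozygous). Seeds are
# spaced so that any read within the substitution budget keeps at least
# one exact seed (pigeonhole), giving full sensitivity.

.refSeqs <- function(reference) {
  if (methods::is(reference, "GenomeAnnotation")) genomeSequences(reference)
  else reference
}

#' Map reads to a reference with a substitution budget
#'
#' Exact multi-seed lookup (one seed per \code{maxSubstitutions + 1}
#' read segment) followed by full-length mismatch counting at every
#' candidate locus, on both strands. Each read is assigned its
#' minimum-mismatch placement when that minimum is at most
#' \code{maxSubstitutions}; reads whose best mismatch count occurs at
#' more than one locus are discarded as ambiguous.
#'
#' @param reads named \link[Biostrings]{DNAStringSet} of equal-length
#'   reads.
#' @param reference \linkS4class{GenomeAnnotation} or DNAStringSet.
#' @param maxSubstitutions maximum mismatches for a valid placement.
#' @return data.frame: \code{readId}, \code{scaffold}, \code{start}
#'   (1-based), \code{strand}, \code{nMismatches}. An attribute
#'   \code{orientedSeq} carries each placed read in reference-forward
#'   orientation for pileup use.
#' @export
mapReads <- function(reads, reference, maxSubstitutions = 2L) {
  seqs <- .refSeqs(reference)
  if (length(reads) == 0L) {
    return(.emptyPlacements())
  }
  rl <- unique(Biostrings::width(reads))
  if (length(rl) != 1L) stop("reads must have equal length", call. = FALSE)
  nSeg <- maxSubstitutions + 1L
  k <- min(32L, rl %/% nSeg)
  if (k < 8L) {
    k <- min(rl, 8L)
    nSeg <- max(1L, rl %/% k)
  }
  offsets <- (seq_len(nSeg) - 1L) * k + 1L
  ids <- names(reads)
  fwd <- as.character(reads)
  rev <- as.character(Biostrings::reverseComplement(reads))

  cand <- list()  # per orientation/scaffold candidate (readIdx, start)
  for (ori in c("+", "-")) {
    rch <- if (ori == "+") fwd else rev
    for (off in offsets) {
      seed <- substr(rch, off, off + k - 1L)
      okSeed <- !grepl("N", seed, fixed = TRUE)
      if (!any(okSeed)) next
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed[okSeed]))
      idxMap <- which(okSeed)
      for (s in seq_along(seqs)) {
        mi <- Biostrings::matchPDict(pd, seqs[[s]])
        st <- Biostrings::startIndex(mi)
        nh <- lengths(st)
        if (sum(nh) == 0L) next
        readIdx <- rep.int(idxMap, nh)
        starts <- unlist(st, use.names = FALSE) - (off - 1L)
        ok <- starts >= 1L & starts + rl - 1L <= Biostrings::width(seqs)[s]
        cand[[length(cand) + 1L]] <- data.frame(
          readIdx = readIdx[ok], scaffold = names(seqs)[s],
          start = starts[ok], strand = ori, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(.emptyPlacements())
  cd <- do.call(rbind, cand)
  cd <- cd[!duplicated(cd[, c("readIdx", "scaffold", "start", "strand")]), ,
           drop = FALSE]

  # mismatch counts: compare oriented read text to the reference window
  cd$nMismatches <- NA_integer_
  for (s in unique(cd$scaffold)) {
    sel <- which(cd$scaffold == s)
    windows <- as.character(Biostrings::DNAStringSet(
      Biostrings::Views(seqs[[s]], start = cd$start[sel], width = rl)))
    oriented <- ifelse(cd$strand[sel] == "+", fwd[cd$readIdx[sel]],
                       rev[cd$readIdx[sel]])
    cd$nMismatches[sel] <- vapply(seq_along(sel), function(i) {
      sum(charToRaw(oriented[i]) != charToRaw(windows[i]))
    }, 0L)
  }
  cd <- cd[cd$nMismatches <= maxSubstitutions, , drop = FALSE]
  if (!nrow(cd)) return(.emptyPlacements())

  # per read: keep the unique minimum-mismatch locus, drop ties
  o <- order(cd$readIdx, cd$nMismatches, cd$scaffold, cd$start)
  cd <- cd[o, , drop = FALSE]
  first <- !duplicated(cd$readIdx)
  bestMm <- cd$nMismatches[first][match(cd$readIdx, cd$readIdx[first])]
  atBest <- cd$nMismatches == bestMm
  nBest <- tabulate(factor(cd$readIdx[atBest],
                           levels = unique(cd$readIdx)))
  uniqueBest <- unique(cd$readIdx)[nBest == 1L]
  out <- cd[first & cd$readIdx %in% uniqueBest, , drop = FALSE]
  oriented <- ifelse(out$strand == "+", fwd[out$readIdx], rev[out$readIdx])
  res <- data.frame(readId = ids[out$readIdx], scaffold = out$scaffold,
                    start = out$start, strand = out$strand,
                    nMismatches = out$nMismatches, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "orientedSeq") <- oriented
  attr(res, "readLength") <- rl
  res
}

.emptyPlacements <- function() {
  res <- data.frame(readId = character(0), scaffold = character(0),
                    start = integer(0), strand = character(0),
                    nMismatches = integer(0), stringsAsFactors = FALSE)
  attr(res, "orientedSeq") <- character(0)
  attr(res, "readLength") <- NA_integer_
  res
}

#' Per-base read depth from placements
#'
#' @param placements placement table from [mapReads()].
#' @param reference the mapped-against reference (for scaffold lengths).
#' @return A named \link[S4Vectors]{RleList}-like list of integer Rle,
#'   one per scaffold.
#' @export
depthProfile <- function(placements, reference) {
  seqs <- .refSeqs(reference)
  rl <- attr(placements, "readLength")
  covs <- lapply(seq_along(seqs), function(s) {
    sel <- placements$scaffold == names(seqs)[s]
    IRanges::coverage(IRanges::IRanges(placements$start[sel], width = rl),
                      width = Biostrings::width(seqs)[s])
  })
  names(covs) <- names(seqs)
  covs
}

#' Call homozygous SNVs from a read pileup
#'
#' A site is an SNV iff its depth is at least \code{minDepth} and the
#' single most frequent non-reference allele reaches
#' \code{minAltFraction} of the depth.
#'
#' @param placements placement table from [mapReads()] (against
#'   \code{reference}).
#' @param reference \linkS4class{GenomeAnnotation} or DNAStringSet.
#' @param minDepth minimum pileup depth at a called site.
#' @param minAltFraction minimum fraction of the top non-reference
#'   allele.
#' @return A \link[GenomicRanges]{GRanges} of width-1 sites with
#'   metadata \code{ref}, \code{alt}, \code{depth}, \code{altFraction}.
#' @export
callSnvs <- function(placements, reference, minDepth = 4L,
                     minAltFraction = 0.9) {
  seqs <- .refSeqs(reference)
  rl <- attr(placements, "readLength")
  oriented <- attr(placements, "orientedSeq")
  if (is.null(oriented) || length(oriented) != nrow(placements)) {
    stop("placements must carry oriented read sequences (use mapReads)",
         call. = FALSE)
  }
  if (!nrow(placements)) {
    return(GenomicRanges::GRanges(ref = character(0), alt = character(0),
                                  depth = integer(0),
                                  altFraction = numeric(0)))
  }
  cov <- depthProfile(placements, reference)
  out <- list()
  for (s in unique(placements$scaffold)) {
    sel <- which(placements$scaffold == s)
    refWin <- as.character(Biostrings::DNAStringSet(
      Biostrings::Views(seqs[[s]], start = placements$start[sel],
                        width = rl)))
    # collect mismatch events (position, alt base) over all reads
    ev <- lapply(seq_along(sel), function(i) {
      a <- charToRaw(oriented[sel[i]])
      b <- charToRaw(refWin[i])
      d <- which(a != b)
      if (!length(d)) return(NULL)
      cbind(pos = placements$start[sel[i]] + d - 1L, alt = as.integer(a[d]))
    })
    ev <- do.call(rbind, ev)
    if (is.null(ev) || !nrow(ev)) next
    key <- paste(ev[, "pos"], ev[, "alt"])
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    pos <- as.integer(parts[, 1L])
    altChar <- rawToChar(as.raw(as.integer(parts[, 2L])), multiple = TRUE)
    altCount <- as.integer(cnt)
    # top non-reference allele per position
    o <- order(pos, -altCount, altChar)
    top <- !duplicated(pos[o])
    pos <- pos[o][top]; altChar <- altChar[o][top]
    altCount <- altCount[o][top]
    depth <- as.integer(cov[[s]][pos])
    refChar <- rawToChar(charToRaw(as.character(seqs[[s]]))[pos],
                         multiple = TRUE)
    keep <- depth >= minDepth & altCount / depth >= minAltFraction &
      altChar != refChar & altChar %in% DNA_BASES
    if (!any(keep)) next
    out[[s]] <- GenomicRanges::GRanges(
      s, IRanges::IRanges(pos[keep], width = 1L),
      ref = refChar[keep], alt = altChar[keep], depth = depth[keep],
      altFraction = altCount[keep] / depth[keep])
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(ref = character(0), alt = character(0),
                                  depth = integer(0),
                                  altFraction = numeric(0)))
  }
  res <- sort(do.call(c, unname(out)))
  GenomeInfoDb::seqlengths(res) <-
    Biostrings::width(seqs)[match(GenomeInfoDb::seqlevels(res), names(seqs))]
  res
}

#' SNV density in fixed non-overlapping windows
#'
#' Tiles each scaffold with non-overlapping windows (10 Mb by default,
#' mirroring the chromosome-scale profile; the final partial window is
#' retained and flagged) and counts SNVs per window. Counts always sum
#' to the total SNV count.
#'
#' @param snvs \link[GenomicRanges]{GRanges} of SNV sites (from
#'   [callSnvs()]).
#' @param scaffoldLengths named integer vector of scaffold lengths, or a
#'   \linkS4class{GenomeAnnotation}.
#' @param window window width in bp.
#' @return A \link[GenomicRanges]{GRanges} of windows with metadata
#'   \code{count} and \code{partial}.
#' @export
windowDensity <- function(snvs, scaffoldLengths, window = 1e7) {
  if (methods::is(scaffoldLengths, "GenomeAnnotation")) {
    seqs <- genomeSequences(scaffoldLengths)
    scaffoldLengths <- stats::setNames(Biostrings::width(seqs), names(seqs))
  }
  .assertScalarIn(window, "window", 1)
  if (length(snvs)) {
    sl <- scaffoldLengths[as.character(GenomeInfoDb::seqnames(snvs))]
    if (anyNA(sl) || any(GenomicRanges::start(snvs) > sl) ||
        any(GenomicRanges::start(snvs) < 1L)) {
      stop("consistency error: SNV position outside scaffold bounds",
           call. = FALSE)
    }
  }
  tiles <- GenomicRanges::tileGenome(scaffoldLengths, tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  if (methods::is(tiles, "GRangesList")) tiles <- unlist(tiles)
  tiles$count <- GenomicRanges::countOverlaps(tiles, snvs,
                                              ignore.strand = TRUE)
  tiles$partial <- GenomicRanges::width(tiles) < window
  tiles
}

#' Ratio of mean windowed SNV density inside vs outside an interval
#'
#' Convenience summary for pericentromere-style density comparisons:
#' windows fully inside the interval (on any scaffold) versus windows
#' fully outside; density is count per bp.
#'
#' @param wd window GRanges from [windowDensity()].
#' @param intervalStart,intervalEnd interval bounds (bp, applied on every
#'   scaffold).
#' @return A list: \code{densityIn}, \code{densityOut}, \code{ratio},
#'   \code{countIn}, \code{countOut}.
#' @export
densityRatio <- function(wd, intervalStart, intervalEnd) {
  inWin <- GenomicRanges::start(wd) >= intervalStart &
    GenomicRanges::end(wd) <= intervalEnd
  outWin <- GenomicRanges::end(wd) < intervalStart |
    GenomicRanges::start(wd) > intervalEnd
  ci <- sum(wd$count[inWin]); li <- sum(GenomicRanges::width(wd)[inWin])
  co <- sum(wd$count[outWin]); lo <- sum(GenomicRanges::width(wd)[outWin])
  di <- if (li > 0) ci / li else NA_real_
  dout <- if (lo > 0) co / lo else NA_real_
  list(densityIn = di, densityOut = dout, ratio = di / dout,
       countIn = ci, countOut = co)
}

#' Covered fraction of gene spans under a depth threshold
#'
#' For each gene, the fraction of its genomic span (introns included)
#' covered at read depth at least \code{minDepth}.
#'
#' @param placements placement table from [mapReads()].
#' @param genome the mapped-against \linkS4class{GenomeAnnotation}.
#' @param minDepth depth at which a base counts as covered.
#' @return data.frame: \code{gene}, \code{geneLength}, \code{coveredBp},
#'   \code{coveredFraction}.
#' @export
geneCoverage <- function(placements, genome, minDepth = 1L) {
  gr <- geneModels(genome)
  cov <- depthProfile(placements, genome)
  rows <- lapply(seq_along(gr), function(i) {
    scn <- as.character(GenomeInfoDb::seqnames(gr))[i]
    v <- cov[[scn]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]]
    len <- GenomicRanges::width(gr)[i]
    cb <- sum(v >= minDepth)
    data.frame(gene = gr$gene_id[i], geneLength = len, coveredBp = cb,
               coveredFraction = cb / len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
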