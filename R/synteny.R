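# Syntenic block chaining from homologous gene pairs, under the two
# published criteria: a block holds >= minBlockGenes gene pairs, and
# fewer than maxGap non-syntenic genes lie between adjacent syntenic
# genes. The gap criterion is enforced on BOTH genomes' gene orders (the
# stricter, reproducible reading). Inverted (monotone-decreasing) chains
# are accepted and flagged.

#' Gene order index of a genome
#'
#' Orders genes by start coordinate within each sequence and assigns
#' 0-based ordinals, the coordinate system of the chain gap criterion.
#'
#' @param genome a \linkS4class{GenomeAnnotation} or a GRanges with a
#'   \code{gene_id} metadata column.
#' @return A data.frame with columns \code{gene}, \code{seq},
#'   \code{ordinal} (0-based, consecutive within \code{seq}),
#'   \code{strand}, \code{start}, \code{end}.
#' @export
geneOrderIndex <- function(genome) {
  gr <- if (methods::is(genome, "GenomeAnnotation")) geneModels(genome) else genome
  if (length(gr) == 0L) {
    return(data.frame(gene = character(0), seq = character(0),
                      ordinal = integer(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  df <- data.frame(gene = gr$gene_id,
                   seq = as.character(GenomeInfoDb::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df <- df[order(df$seq, df$start), , drop = FALSE]
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$seq,
                           FUN = function(i) seq_along(i) - 1L)
  rownames(df) <- NULL
  df[, c("gene", "seq", "ordinal", "strand", "start", "end")]
}

# chain comparator: longer first, then smaller summed gap, then leftmost
# A start, then leftmost B start, then same-orientation before inverted,
# then lexicographically smallest (aOrd, bOrd) member sequence
.chainBetter <- function(x, y) {
  if (is.null(y)) return(TRUE)
  if (x$n != y$n) return(x$n > y$n)
  if (x$sumGap != y$sumGap) return(x$sumGap < y$sumGap)
  if (x$aOrd[1L] != y$aOrd[1L]) return(x$aOrd[1L] < y$aOrd[1L])
  if (x$bOrd[1L] != y$bOrd[1L]) return(x$bOrd[1L] < y$bOrd[1L])
  if (x$orientation != y$orientation) return(x$orientation == "same")
  keyx <- as.vector(rbind(x$aOrd, x$bOrd))
  keyy <- as.vector(rbind(y$aOrd, y$bOrd))
  cmp <- keyx - keyy
  nz <- which(cmp != 0)
  if (length(nz)) return(cmp[nz[1L]] < 0)
  FALSE
}

# best valid chain among pairs (a, b ordinals) for one orientation, by
# longest-monotone-subsequence DP with the gap constraint on both sides
.bestChainDP <- function(a, b, maxGap, orientation) {
  n <- length(a)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  len <- rep(1L, n)
  gapsum <- rep(0L, n)
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a[i] <= a[j]) next
      gA <- a[i] - a[j] - 1L
      if (gA >= maxGap) next
      gB <- if (orientation == "same") b[i] - b[j] - 1L else b[j] - b[i] - 1L
      if (gB < 0L || gB >= maxGap) next
      cl <- len[j] + 1L
      cg <- gapsum[j] + gA + gB
      better <- FALSE
      if (cl > len[i]) better <- TRUE
      else if (cl == len[i] && cg < gapsum[i]) better <- TRUE
      else if (cl == len[i] && cg == gapsum[i] && !is.na(pred[i])) {
        # resolve by lexicographic path comparison from the start
        pj <- .tracePath(j, pred); pi0 <- .tracePath(pred[i], pred)
        keyj <- as.vector(rbind(a[pj], b[pj]))
        keyi <- as.vector(rbind(a[pi0], b[pi0]))
        cmp <- keyj - keyi
        nz <- which(cmp != 0)
        if (length(nz) && cmp[nz[1L]] < 0) better <- TRUE
      }
      if (better) {
        len[i] <- cl; gapsum[i] <- cg; pred[i] <- j
      }
    }
  }
  best <- NULL
  for (i in seq_len(n)) {
    path <- .tracePath(i, pred)
    cand <- list(n = len[i], sumGap = gapsum[i], aOrd = a[path],
                 bOrd = b[path], idx = ord[path], orientation = orientation)
    if (.chainBetter(cand, best)) best <- cand
  }
  best
}

.tracePath <- function(i, pred) {
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- pred[i]
  }
  path
}

#' Call syntenic gene blocks from a homolog-pair table
#'
#' Chains homolog pairs per (sequence A, sequence B) combination by
#' dynamic programming over gene ordinals. A valid chain is strictly
#' monotone in both gene orders (increasing on both for \code{same}
#' orientation, decreasing on the B side for \code{inverted}) with fewer
#' than \code{maxGap} intervening genes between adjacent members on both
#' sides. Blocks of at least \code{minBlockGenes} members are extracted
#' greedily (best chain first, deterministic tie-breaks), and no gene
#' appears in two blocks of the same sequence combination.
#'
#' @param pairs data.frame with columns \code{geneA}, \code{geneB} (as
#'   from [allVsAllHomologs()]).
#' @param orderA,orderB gene order indexes from [geneOrderIndex()].
#' @param minBlockGenes minimum gene pairs per block (criterion i).
#' @param maxGap strict upper bound on intervening non-syntenic genes
#'   between adjacent members (criterion ii).
#' @param allowInversions accept monotone-decreasing chains on the B
#'   side, flagged \code{orientation == "inverted"}.
#' @return A data.frame, one row per block: \code{seqA}, \code{seqB},
#'   \code{orientation}, \code{nGenes}, \code{sumGap},
#'   \code{maxInternalGap}, coordinate spans on both genomes, and a
#'   \code{members} list column of per-block data.frames (\code{geneA},
#'   \code{geneB}, ordinals).
#' @export
callBlocks <- function(pairs, orderA, orderB, minBlockGenes = 3L,
                       maxGap = 5L, allowInversions = TRUE) {
  if (!nrow(pairs)) return(.emptyBlocks())
  ia <- match(pairs$geneA, orderA$gene)
  ib <- match(pairs$geneB, orderB$gene)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(pairs$geneA[is.na(ia)], pairs$geneB[is.na(ib)]))
    stop("consistency error: gene(s) in pairs absent from annotations: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
                   seqA = orderA$seq[ia], aOrd = orderA$ordinal[ia],
                   startA = orderA$start[ia], endA = orderA$end[ia],
                   seqB = orderB$seq[ib], bOrd = orderB$ordinal[ib],
                   startB = orderB$start[ib], endB = orderB$end[ib],
                   stringsAsFactors = FALSE)
  blocks <- list()
  for (grp in split(df, paste(df$seqA, df$seqB, sep = "\r"))) {
    avail <- grp
    repeat {
      if (nrow(avail) < minBlockGenes) break
      orientations <- if (allowInversions) c("same", "inverted") else "same"
      best <- NULL
      for (o in orientations) {
        cand <- .bestChainDP(avail$aOrd, avail$bOrd, maxGap, o)
        if (!is.null(cand) && .chainBetter(cand, best)) best <- cand
      }
      if (is.null(best) || best$n < minBlockGenes) break
      mem <- avail[best$idx, , drop = FALSE]
      gA <- diff(mem$aOrd) - 1L
      gB <- abs(diff(mem$bOrd)) - 1L
      blocks[[length(blocks) + 1L]] <- data.frame(
        seqA = mem$seqA[1L], seqB = mem$seqB[1L],
        orientation = best$orientation, nGenes = best$n,
        sumGap = best$sumGap,
        maxInternalGap = if (best$n > 1L) max(c(gA, gB)) else 0L,
        startA = min(mem$startA), endA = max(mem$endA),
        startB = min(mem$startB), endB = max(mem$endB),
        members = I(list(mem[, c("geneA", "geneB", "aOrd", "bOrd")])),
        stringsAsFactors = FALSE)
      avail <- avail[!(avail$geneA %in% mem$geneA |
                       avail$geneB %in% mem$geneB), , drop = FALSE]
    }
  }
  if (!length(blocks)) return(.emptyBlocks())
  out <- do.call(rbind, blocks)
  out <- out[order(out$seqA, out$seqB, out$startA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyBlocks <- function() {
  data.frame(seqA = character(0), seqB = character(0),
             orientation = character(0), nGenes = integer(0),
             sumGap = integer(0), maxInternalGap = integer(0),
             startA = integer(0), endA = integer(0),
             startB = integer(0), endB = integer(0),
             members = I(list()), stringsAsFactors = FALSE)
}

#' Genes contained in syntenic blocks, per genotype
#'
#' The union of block member genes; downstream this is the exclusion set
#' of the genotype-specific gene caller (collinear genes cannot be
#' specific).
#'
#' @param blocks block table from [callBlocks()].
#' @return A list with character vectors \code{genesA} and \code{genesB}.
#' @export
syntenicGeneSet <- function(blocks) {
  if (!nrow(blocks)) return(list(genesA = character(0), genesB = character(0)))
  mem <- do.call(rbind, blocks$members)
  list(genesA = unique(mem$geneA), genesB = unique(mem$geneB))
}

#' Summary statistics of a block set
#'
#' @param blocks block table from [callBlocks()].
#' @return A list: \code{nBlocks}, \code{nGenesTotal} (gene pairs summed
#'   over blocks), \code{meanGenesPerBlock}, and the latter rounded to
#'   the nearest integer as \code{meanRounded}. An empty block list
#'   yields zeros.
#' @export
blockSummary <- function(blocks) {
  if (!nrow(blocks)) {
    return(list(nBlocks = 0L, nGenesTotal = 0L, meanGenesPerBlock = 0,
                meanRounded = 0L))
  }
  syntenySummary(sum(blocks$nGenes), nrow(blocks))
}

#' Block summary from totals
#'
#' The printed-summary arithmetic: mean genes per block from the total
#' gene and block counts (e.g. 9718 genes in 1558 blocks give 6.24,
#' printed as an average of six genes per block).
#'
#' @param nGenesTotal total genes in blocks.
#' @param nBlocks number of blocks.
#' @return A list as in [blockSummary()].
#' @examples
#' syntenySummary(9718, 1558)
#' @export
syntenySummary <- function(nGenesTotal, nBlocks) {
  .assertScalarIn(nBlocks, "nBlocks", 1)
  m <- nGenesTotal / nBlocks
  list(nBlocks = as.integer(nBlocks), nGenesTotal = as.integer(nGenesTotal),
       meanGenesPerBlock = m, meanRounded = as.integer(round(m)))
}
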