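# Two-genotype genome simulator with planted ground truth.
#
# Genotype A is built first (intergenic spacer / gene / spacer ... layout,
# intronless coding genes made of sense codons). Genotype B derives from A by
# (i) whole-gene deletion of the planted A-specific genes (or, in "partial"
# mode, replacement of their locus by unrelated sequence of equal length),
# (ii) insertion of newly drawn B-specific genes into intergenic gaps, and
# (iii) planted substitutions at snvRate per site, multiplied inside the
# pericentromere-like interval. Gene order is preserved, so true syntenic
# blocks are maximal runs of shared genes.

.senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.randomCodingString <- function(nCodon, codons = .senseCodons()) {
  paste(sample(codons, nCodon, replace = TRUE), collapse = "")
}

# posA -> posB for positions surviving deletion, given deletion spans and
# insertion anchors (insertion of insLen bases immediately after anchor)
.mapAtoB <- function(pos, delSpans, insAnchor, insLen) {
  shift <- numeric(length(pos))
  if (length(insAnchor)) {
    shift <- shift + vapply(pos, function(p) sum(insLen[insAnchor < p]), 0)
  }
  if (!is.null(delSpans) && length(delSpans)) {
    w <- IRanges::width(delSpans)
    e <- IRanges::end(delSpans)
    shift <- shift - vapply(pos, function(p) sum(w[e < p]), 0)
  }
  as.integer(pos + shift)
}

#' Simulate a two-genotype genome pair with recorded truth
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return A list with elements \code{genomeA}, \code{genomeB}
#'   (\linkS4class{GenomeAnnotation}) and \code{truth}
#'   (\linkS4class{GenomeTruth}).
#' @examples
#' sim <- simulateGenomePair(simulationSpec(seed = 7, nScaffolds = 1,
#'   nGenes = 10, scaffoldLength = 40000L, nSpecificA = 2, nSpecificB = 1))
#' sim$genomeA
#' truthSpecificA(sim$truth)
#' @export
simulateGenomePair <- function(spec) {
  methods::validObject(spec)
  set.seed(stageSeed(spec@seed, "genome"))
  gl <- spec@geneLength
  ig <- spec@intergenicLength

  gper <- rep(spec@nGenes %/% spec@nScaffolds, spec@nScaffolds)
  extra <- spec@nGenes %% spec@nScaffolds
  if (extra > 0L) gper[seq_len(extra)] <- gper[seq_len(extra)] + 1L
  need <- gper * (gl + ig) + ig
  if (any(need > spec@scaffoldLength)) {
    stop("sizing error: gene layout does not fit 'scaffoldLength' ",
         sprintf("(need up to %d bp, have %d)", max(need),
                 spec@scaffoldLength), call. = FALSE)
  }

  scafNames <- sprintf("scf%02d", seq_len(spec@nScaffolds))
  codons <- .senseCodons()

  aChar <- character(spec@nScaffolds)
  geneRows <- vector("list", spec@nScaffolds)
  geneCdna <- character(0)
  gid <- 0L
  for (s in seq_len(spec@nScaffolds)) {
    g <- gper[s]
    cod <- vapply(seq_len(g), function(i) .randomCodingString(gl %/% 3L, codons), "")
    strands <- if (spec@randomStrand) sample(c("+", "-"), g, replace = TRUE) else rep("+", g)
    genomic <- ifelse(strands == "-",
                      vapply(cod, function(x)
                        as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(x))), ""),
                      cod)
    spacers <- vapply(seq_len(g + 1L), function(i) randomDnaString(ig), "")
    pieces <- character(2L * g + 1L)
    pieces[seq(1L, 2L * g + 1L, by = 2L)] <- spacers
    pieces[seq(2L, 2L * g, by = 2L)] <- genomic
    body <- paste(pieces, collapse = "")
    tailLen <- spec@scaffoldLength - nchar(body)
    aChar[s] <- paste0(body, if (tailLen > 0L) randomDnaString(tailLen) else "")
    starts <- ig + (seq_len(g) - 1L) * (gl + ig) + 1L
    ids <- sprintf("gA_%04d", gid + seq_len(g))
    gid <- gid + g
    geneRows[[s]] <- data.frame(gene_id = ids, scaffold = scafNames[s],
                                start = starts, end = starts + gl - 1L,
                                strand = strands, stringsAsFactors = FALSE)
    geneCdna <- c(geneCdna, stats::setNames(cod, ids))
  }
  genesA <- do.call(rbind, geneRows)

  specificA <- if (spec@nSpecificA > 0L) {
    sort(sample(genesA$gene_id, spec@nSpecificA))
  } else character(0)
  if (spec@nSpecificA > spec@nGenes) {
    stop("more A-specific genes requested than genes simulated", call. = FALSE)
  }

  # draw B-specific gene payloads and scatter them over scaffolds
  bIns <- NULL
  if (spec@nSpecificB > 0L) {
    bScaf <- sort(sample(seq_len(spec@nScaffolds), spec@nSpecificB, replace = TRUE))
    bIns <- data.frame(scaffold = scafNames[bScaf],
                       seq = vapply(seq_len(spec@nSpecificB), function(i)
                         .randomCodingString(gl %/% 3L, codons), ""),
                       strand = if (spec@randomStrand)
                         sample(c("+", "-"), spec@nSpecificB, replace = TRUE)
                       else rep("+", spec@nSpecificB),
                       stringsAsFactors = FALSE)
  }

  bChar <- character(spec@nScaffolds)
  names(bChar) <- scafNames
  sharedRows <- vector("list", spec@nScaffolds)
  insRows <- vector("list", spec@nScaffolds)
  snvRows <- vector("list", spec@nScaffolds)
  delBySc <- vector("list", spec@nScaffolds)
  insBySc <- vector("list", spec@nScaffolds)

  for (s in seq_len(spec@nScaffolds)) {
    scn <- scafNames[s]
    ga <- genesA[genesA$scaffold == scn, , drop = FALSE]
    delGenes <- ga[ga$gene_id %in% specificA, , drop = FALSE]
    L <- nchar(aChar[s])

    delSpans <- IRanges::IRanges()
    if (spec@specificMode == "deletion" && nrow(delGenes)) {
      delSpans <- IRanges::IRanges(delGenes$start, delGenes$end)
    }

    # candidate insertion anchors: inside intergenic gaps, clear of genes
    myIns <- if (!is.null(bIns)) bIns[bIns$scaffold == scn, , drop = FALSE] else NULL
    insAnchor <- integer(0)
    insSeq <- character(0)
    insStrand <- character(0)
    if (!is.null(myIns) && nrow(myIns)) {
      geneSpans <- IRanges::IRanges(ga$start, ga$end)
      free <- IRanges::setdiff(IRanges::IRanges(1L, L), geneSpans)
      free <- free[IRanges::width(free) > 20L]
      anchors <- unlist(lapply(seq_len(length(free)), function(i) {
        seq(IRanges::start(free)[i] + 10L, IRanges::end(free)[i] - 10L)
      }))
      insAnchor <- sort(sample(anchors, nrow(myIns)))
      insSeq <- myIns$seq
      insStrand <- myIns$strand
    }

    # assemble B: walk kept intervals, splicing insertions at their anchors
    kept <- IRanges::setdiff(IRanges::IRanges(1L, L), delSpans)
    pieces <- character(0)
    bLen <- 0L
    insStart <- integer(length(insAnchor))
    ki <- 1L
    for (k in seq_len(length(kept))) {
      ks <- IRanges::start(kept)[k]; ke <- IRanges::end(kept)[k]
      prev <- ks
      while (ki <= length(insAnchor) && insAnchor[ki] >= ks && insAnchor[ki] <= ke) {
        a <- insAnchor[ki]
        pieces <- c(pieces, substr(aChar[s], prev, a))
        bLen <- bLen + (a - prev + 1L)
        gseq <- if (insStrand[ki] == "-")
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(insSeq[ki])))
        else insSeq[ki]
        pieces <- c(pieces, gseq)
        insStart[ki] <- bLen + 1L
        bLen <- bLen + nchar(gseq)
        prev <- a + 1L
        ki <- ki + 1L
      }
      if (prev <= ke) {
        pieces <- c(pieces, substr(aChar[s], prev, ke))
        bLen <- bLen + (ke - prev + 1L)
      }
    }
    bRaw <- charToRaw(paste(pieces, collapse = ""))

    # partial mode: the A-specific locus stays but diverges beyond recognition
    if (spec@specificMode == "partial" && nrow(delGenes)) {
      for (i in seq_len(nrow(delGenes))) {
        posB <- .mapAtoB(delGenes$start[i], delSpans, insAnchor,
                         nchar(insSeq))  # delSpans empty in this mode
        repl <- randomDnaString(delGenes$end[i] - delGenes$start[i] + 1L)
        bRaw[seq(posB, posB + nchar(repl) - 1L)] <- charToRaw(repl)
      }
    }

    # planted SNVs on surviving A positions
    rate <- rep(spec@snvRate, L)
    periLo <- max(1, min(L, spec@periStart))
    periHi <- max(1, min(L, spec@periEnd))
    if (spec@periEnd >= 1 && spec@periStart <= L) {
      rate[periLo:periHi] <- spec@snvRate * spec@periMultiplier
    }
    hit <- which(runif(L) < rate)
    if (length(delSpans)) {
      inDel <- IRanges::overlapsAny(IRanges::IRanges(hit, hit), delSpans)
      hit <- hit[!inDel]
    }
    if (spec@specificMode == "partial" && nrow(delGenes)) {
      inRepl <- IRanges::overlapsAny(IRanges::IRanges(hit, hit),
                                     IRanges::IRanges(delGenes$start, delGenes$end))
      hit <- hit[!inRepl]
    }
    snvDf <- data.frame(scaffold = character(0), posA = integer(0),
                        posB = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
    if (length(hit)) {
      posB <- .mapAtoB(hit, delSpans, insAnchor, nchar(insSeq))
      sub <- .substituteBases(bRaw, posB)
      bRaw <- sub$raw
      snvDf <- data.frame(scaffold = scn, posA = hit, posB = posB,
                          ref = sub$ref, alt = sub$alt,
                          stringsAsFactors = FALSE)
    }

    # shared gene models in B coordinates
    shared <- ga[!(ga$gene_id %in% specificA), , drop = FALSE]
    if (nrow(shared)) {
      shared$startB <- .mapAtoB(shared$start, delSpans, insAnchor, nchar(insSeq))
      shared$endB <- .mapAtoB(shared$end, delSpans, insAnchor, nchar(insSeq))
    } else {
      shared$startB <- integer(0); shared$endB <- integer(0)
    }

    # extra synonymous divergence at fourfold-degenerate third positions
    if (spec@orthologKs > 0 && nrow(shared)) {
      fourfold <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")
      pKs <- .jcDiffProb(spec@orthologKs)
      for (i in seq_len(nrow(shared))) {
        st <- shared$startB[i]; en <- shared$endB[i]
        gseq <- rawToChar(bRaw[st:en])
        if (shared$strand[i] == "-") {
          gseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
        }
        n3 <- seq(3L, nchar(gseq), by = 3L)
        pref <- substring(gseq, n3 - 2L, n3 - 1L)
        elig <- n3[pref %in% fourfold]
        pick <- elig[runif(length(elig)) < pKs]
        if (!length(pick)) next
        gpos <- if (shared$strand[i] == "+") st + pick - 1L else en - pick + 1L
        sub <- .substituteBases(bRaw, gpos)
        bRaw <- sub$raw
        posA <- .mapBtoAFromPos(gpos, delSpans, insAnchor, nchar(insSeq))
        refA <- substring(aChar[s], posA, posA)
        keepRow <- sub$alt != refA  # a site may coincide with a planted SNV
        snvDf <- rbind(snvDf,
                       data.frame(scaffold = scn, posA = posA[keepRow],
                                  posB = gpos[keepRow], ref = refA[keepRow],
                                  alt = sub$alt[keepRow],
                                  stringsAsFactors = FALSE))
      }
      snvDf <- snvDf[!duplicated(snvDf$posA, fromLast = TRUE), , drop = FALSE]
      snvDf <- snvDf[order(snvDf$posA), , drop = FALSE]
    }

    bChar[s] <- rawToChar(bRaw)
    sharedRows[[s]] <- shared
    snvRows[[s]] <- snvDf
    if (length(insAnchor)) {
      insRows[[s]] <- data.frame(scaffold = scn, start = insStart,
                                 end = insStart + nchar(insSeq) - 1L,
                                 strand = insStrand, seq = insSeq,
                                 stringsAsFactors = FALSE)
    }
  }

  seqsA <- Biostrings::DNAStringSet(stats::setNames(aChar, scafNames))
  grA <- GenomicRanges::GRanges(genesA$scaffold,
                                IRanges::IRanges(genesA$start, genesA$end),
                                strand = genesA$strand,
                                gene_id = genesA$gene_id)
  genomeA <- GenomeAnnotation(seqsA, grA,
                              Biostrings::DNAStringSet(geneCdna))

  shared <- do.call(rbind, sharedRows)
  ins <- do.call(rbind, insRows)
  bTab <- data.frame(scaffold = shared$scaffold, start = shared$startB,
                     end = shared$endB, strand = shared$strand,
                     geneA = shared$gene_id, stringsAsFactors = FALSE)
  if (!is.null(ins) && nrow(ins)) {
    bTab <- rbind(bTab, data.frame(scaffold = ins$scaffold, start = ins$start,
                                   end = ins$end, strand = ins$strand,
                                   geneA = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  bTab <- bTab[order(bTab$scaffold, bTab$start), , drop = FALSE]
  bTab$gene_id <- sprintf("gB_%04d", seq_len(nrow(bTab)))
  grB <- GenomicRanges::GRanges(bTab$scaffold,
                                IRanges::IRanges(bTab$start, bTab$end),
                                strand = bTab$strand, gene_id = bTab$gene_id)
  genomeB <- GenomeAnnotation(Biostrings::DNAStringSet(bChar), grB)

  orthoIdx <- !is.na(bTab$geneA)
  truth <- methods::new("GenomeTruth",
    specificA = specificA,
    specificB = bTab$gene_id[!orthoIdx],
    snv = {
      d <- do.call(rbind, snvRows)
      rownames(d) <- NULL
      d
    },
    orthologMap = data.frame(geneA = bTab$geneA[orthoIdx],
                             geneB = bTab$gene_id[orthoIdx],
                             ks = spec@orthologKs,
                             stringsAsFactors = FALSE),
    ltrAges = numeric(0),
    tissueSpecific = data.frame(gene = character(0), tissue = character(0),
                                stringsAsFactors = FALSE))
  list(genomeA = genomeA, genomeB = genomeB, truth = truth)
}

# inverse of .mapAtoB for positions that exist in both genomes
.mapBtoAFromPos <- function(posB, delSpans, insAnchor, insLen) {
  bInsEnd <- if (length(insAnchor)) {
    .mapAtoB(insAnchor, delSpans, insAnchor, insLen) + insLen
  } else integer(0)
  bDelPt <- if (!is.null(delSpans) && length(delSpans)) {
    .mapAtoB(IRanges::end(delSpans) + 1L, delSpans, insAnchor, insLen)
  } else integer(0)
  delW <- if (length(bDelPt)) IRanges::width(delSpans) else integer(0)
  vapply(posB, function(p) {
    as.integer(p - sum(insLen[bInsEnd < p]) + sum(delW[bDelPt <= p]))
  }, 1L)
}

#' Simulate uniform-coverage single-end reads
#'
#' Reads are drawn uniformly along each scaffold at the requested fold
#' coverage, from both strands, with i.i.d. substitution errors. Read
#' names encode their origin (\code{scaffold|pos|strand}) so tests can
#' verify placements.
#'
#' @param genome a \linkS4class{GenomeAnnotation} (or DNAStringSet).
#' @param spec a \linkS4class{SimulationSpec} (uses \code{readLength},
#'   \code{readDepth}, \code{readErrorRate}, \code{seed}).
#' @param seedStage label mixed into the sub-seed so that read sets drawn
#'   from different genomes under one run seed are independent.
#' @return A named \link[Biostrings]{DNAStringSet} of reads.
#' @export
simulateReads <- function(genome, spec, seedStage = "reads") {
  seqs <- if (methods::is(genome, "GenomeAnnotation")) genomeSequences(genome) else genome
  if (spec@readDepth <= 0) stop("parameter error: 'readDepth' must be > 0", call. = FALSE)
  rl <- spec@readLength
  if (any(Biostrings::width(seqs) < rl)) {
    stop("'readLength' exceeds a scaffold length", call. = FALSE)
  }
  set.seed(stageSeed(spec@seed, seedStage))
  out <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    L <- Biostrings::width(seqs)[s]
    n <- round(spec@readDepth * L / rl)
    pos <- sample.int(L - rl + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rd <- Biostrings::DNAStringSet(
      Biostrings::Views(seqs[[s]], start = pos, width = rl))
    neg <- strand == "-"
    if (any(neg)) rd[neg] <- Biostrings::reverseComplement(rd[neg])
    if (spec@readErrorRate > 0) {
      nerr <- rbinom(n, rl, spec@readErrorRate)
      idx <- which(nerr > 0L)
      if (length(idx)) {
        ch <- as.character(rd[idx])
        for (k in seq_along(idx)) {
          p <- sample.int(rl, nerr[idx[k]])
          r <- charToRaw(ch[k])
          r <- .substituteBases(r, p)$raw
          ch[k] <- rawToChar(r)
        }
        rd[idx] <- Biostrings::DNAStringSet(ch)
      }
    }
    names(rd) <- sprintf("%s|%d|%s|r%07d", names(seqs)[s], pos, strand,
                         seq_len(n))
    out[[s]] <- rd
  }
  do.call(c, out)
}

#' Simulate LTR retrotransposon element pairs of known age
#'
#' Each element's two LTRs start identical and diverge under a
#' Jukes-Cantor process so that the expected substitutions per site
#' equal \eqn{2 r T} for true age \eqn{T} (years) and clock rate
#' \eqn{r} (substitutions per site per year).
#'
#' @param spec a \linkS4class{SimulationSpec} (uses \code{nLtrPairs},
#'   \code{ltrAges}, \code{ltrLength}, \code{ltrRate}, \code{seed}).
#' @return A list with \code{seqs} (DNAStringSet, names
#'   \code{ltrNNN_5p}/\code{ltrNNN_3p}) and \code{ages} (named numeric,
#'   MYA).
#' @export
simulateLtrPairs <- function(spec) {
  if (any(spec@ltrAges < 0)) stop("'ltrAges' must be non-negative", call. = FALSE)
  ages <- rep(spec@ltrAges, length.out = spec@nLtrPairs)
  K <- 2 * spec@ltrRate * ages * 1e6
  p <- .jcDiffProb(K)
  if (any(!is.finite(p)) || any(p >= 0.75 - 1e-12)) {
    stop("saturation: requested age implies >= 0.75 expected per-site ",
         "divergence; Jukes-Cantor correction undefined", call. = FALSE)
  }
  set.seed(stageSeed(spec@seed, "ltr"))
  L <- spec@ltrLength
  seqs <- character(2L * spec@nLtrPairs)
  ids <- sprintf("ltr%03d", seq_len(spec@nLtrPairs))
  for (i in seq_len(spec@nLtrPairs)) {
    base <- randomDnaString(L)
    r <- charToRaw(base)
    hit <- which(runif(L) < p[i])
    r <- .substituteBases(r, hit)$raw
    seqs[2L * i - 1L] <- base
    seqs[2L * i] <- rawToChar(r)
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste0(rep(ids, each = 2L), c("_5p", "_3p"))
  list(seqs = dss, ages = stats::setNames(ages, ids))
}

#' Simulate a tissue x replicate count matrix with planted specific genes
#'
#' Counts are negative binomial with a shared dispersion; planted
#' tissue-specific genes have their mean multiplied by \code{foldChange}
#' in exactly one tissue. With \code{foldChange = 1} no gene is labelled
#' specific.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return A list with \code{counts} (genes x samples integer matrix),
#'   \code{tissueMap} (named character, sample to tissue) and
#'   \code{truth} (data.frame \code{gene}, \code{tissue}).
#' @export
simulateCounts <- function(spec) {
  if (length(spec@tissues) < 2L || spec@repsPerTissue < 2L) {
    stop("need >= 2 tissues and >= 2 replicates per tissue", call. = FALSE)
  }
  if (spec@nbDispersion <= 0) {
    stop("parameter error: 'nbDispersion' must be > 0", call. = FALSE)
  }
  set.seed(stageSeed(spec@seed, "counts"))
  genes <- sprintf("gA_%04d", seq_len(spec@nGenes))
  samples <- as.vector(t(outer(spec@tissues, seq_len(spec@repsPerTissue),
                               function(t, r) paste0(t, "_", r))))
  tissueMap <- stats::setNames(rep(spec@tissues, each = spec@repsPerTissue),
                               samples)
  baseMean <- rlnorm(spec@nGenes, spec@exprMeanLog, spec@exprSdLog)
  mu <- matrix(baseMean, nrow = spec@nGenes, ncol = length(samples),
               dimnames = list(genes, samples))
  nSpec <- if (spec@foldChange > 1) {
    round(spec@specificFractionExpr * spec@nGenes)
  } else 0L
  truth <- data.frame(gene = character(0), tissue = character(0),
                      stringsAsFactors = FALSE)
  if (nSpec > 0L) {
    sg <- sample(genes, nSpec)
    st <- sample(spec@tissues, nSpec, replace = TRUE)
    for (i in seq_len(nSpec)) {
      mu[sg[i], tissueMap[samples] == st[i]] <-
        mu[sg[i], tissueMap[samples] == st[i]] * spec@foldChange
    }
    truth <- data.frame(gene = sg, tissue = st, stringsAsFactors = FALSE)
    truth <- truth[order(truth$gene), , drop = FALSE]
    rownames(truth) <- NULL
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec@nbDispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  list(counts = counts, tissueMap = tissueMap, truth = truth)
}
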