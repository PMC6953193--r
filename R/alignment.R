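# Seeded local alignment primitives: exact k-mer seeds, banded
# Smith-Waterman extension (linear gap penalty, compiled), identity over
# aligned columns and coverage over the query. The original study's
# E-value gates are replaced by score/identity/coverage gates, which are
# the binding decision boundaries of the downstream classifications.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

.detectAlphabet <- function(x) {
  ch <- unique(strsplit(x, "")[[1]])
  if (all(ch %in% DNA_ALPHABET)) return("dna")
  if (all(ch %in% AA_ALPHABET)) return("protein")
  stop("input error: sequence contains characters outside the DNA and ",
       "amino-acid alphabets", call. = FALSE)
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# k-mer start positions (1-based) of a target sequence, keyed by k-mer
.kmerIndex <- function(targetChar, k) {
  n <- nchar(targetChar) - k + 1L
  if (n < 1L) return(list())
  km <- substring(targetChar, seq_len(n), seq_len(n) + k - 1L)
  split(seq_len(n), km)
}

# seed diagonals (0-based target start minus query start) shared between
# query and an indexed target, clustered so that one banded extension
# covers each cluster; returns diagonals ordered by seed support
.seedDiagonals <- function(qChar, index, k, band, maxCandidates = 16L) {
  m <- nchar(qChar)
  nq <- m - k + 1L
  if (nq < 1L || length(index) == 0L) return(integer(0))
  qk <- substring(qChar, seq_len(nq), seq_len(nq) + k - 1L)
  hit <- index[qk]
  nh <- lengths(hit)
  if (sum(nh) == 0L) return(integer(0))
  qpos <- rep.int(seq_len(nq), nh)
  tpos <- unlist(hit, use.names = FALSE)
  diag <- tpos - qpos
  tab <- sort(table(diag), decreasing = TRUE)
  cand <- as.integer(names(tab))
  sel <- integer(0)
  for (d in cand) {
    if (length(sel) >= maxCandidates) break
    if (!length(sel) || all(abs(sel - d) > band)) sel <- c(sel, d)
  }
  sel
}

# run one banded extension per candidate diagonal; coordinates 1-based
.extendDiagonals <- function(qChar, tChar, diags, match, mismatch, gap, band) {
  m <- nchar(qChar)
  n <- nchar(tChar)
  res <- lapply(diags, function(d) {
    ws <- max(1L, d + 1L - band - 2L)
    we <- min(n, d + m + band + 2L)
    if (ws > n || we < 1L || we < ws) return(NULL)
    r <- .bandedLocalCpp(qChar, substr(tChar, ws, we), match, mismatch, gap,
                         d - (ws - 1L), band)
    if (r$score <= 0L) return(NULL)
    data.frame(qstart = r$qstart, qend = r$qend,
               tstart = r$tstart + ws - 1L, tend = r$tend + ws - 1L,
               score = r$score, matches = r$matches, alncols = r$alncols)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) return(NULL)
  res[!duplicated(res[, c("qstart", "qend", "tstart", "tend")]), , drop = FALSE]
}

# all candidate local alignments of one query against one indexed target,
# searching the reverse strand for DNA; spans are target-forward, query
# spans refer to the original query orientation
.seedExtendAll <- function(qChar, tChar, tIndex, k, match, mismatch, gap,
                           band, bothStrands = TRUE, alphabet = "dna") {
  m <- nchar(qChar)
  strands <- "+"
  if (alphabet == "dna" && bothStrands) strands <- c("+", "-")
  out <- NULL
  for (st in strands) {
    q <- if (st == "-") .revcompChar(qChar) else qChar
    diags <- .seedDiagonals(q, tIndex, k, band)
    if (!length(diags)) next
    r <- .extendDiagonals(q, tChar, diags, match, mismatch, gap, band)
    if (is.null(r)) next
    if (st == "-") {
      qs <- m - r$qend + 1L
      qe <- m - r$qstart + 1L
      r$qstart <- qs
      r$qend <- qe
    }
    r$strand <- st
    out <- rbind(out, r)
  }
  if (is.null(out) || !nrow(out)) return(NULL)
  out$identity <- out$matches / out$alncols
  out$coverage <- (out$qend - out$qstart + 1L) / m
  out
}

#' Seeded banded local alignment of two sequences
#'
#' Finds the highest-scoring local alignment reachable from an exact
#' k-mer seed by banded Smith-Waterman extension with a linear gap
#' penalty. Identity is the fraction of matching columns over aligned
#' columns; coverage is the aligned query length over the total query
#' length. \code{N}/\code{X} never count as a match. On substitution-only
#' divergence the result equals the optimal (full dynamic programming)
#' local alignment whenever the band covers the optimal path.
#'
#' @param query,target character strings or XString/XStringSet of length
#'   one, DNA or protein.
#' @param match,mismatch,gap scoring parameters (linear gap penalty).
#' @param seedLength exact-seed length; default 15 for DNA, 5 for protein.
#' @param band half-width of the extension band around a seed diagonal.
#' @param minScore alignments scoring below this are reported as absent.
#' @param bothStrands also search the reverse strand (DNA only); hits are
#'   reported in forward target coordinates with \code{strand == "-"}.
#' @param queryId,targetId identifiers copied into the result.
#' @return A one-row data.frame (query, target, qstart, qend, tstart,
#'   tend, strand, score, identity, coverage, matches, alncols;
#'   coordinates 1-based inclusive), or \code{NULL} when no alignment at
#'   or above \code{minScore} is found.
#' @examples
#' alignLocal("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
#'            seedLength = 8, minScore = 10)
#' @export
alignLocal <- function(query, target, match = 2L, mismatch = -3L, gap = -5L,
                       seedLength = NULL, band = 32L, minScore = 30L,
                       bothStrands = TRUE,
                       queryId = "query", targetId = "target") {
  q <- .asSeqChar(query)
  t <- .asSeqChar(target)
  if (nchar(q) == 0L || nchar(t) == 0L) {
    stop("input error: empty sequence", call. = FALSE)
  }
  alpha <- .detectAlphabet(paste0(q, t))
  if (is.null(seedLength)) seedLength <- if (alpha == "dna") 15L else 5L
  idx <- .kmerIndex(t, seedLength)
  r <- .seedExtendAll(q, t, idx, seedLength, match, mismatch, gap, band,
                      bothStrands, alpha)
  if (is.null(r)) return(NULL)
  r <- r[order(-r$score, r$strand, r$tstart), , drop = FALSE]
  best <- r[1L, , drop = FALSE]
  if (best$score < minScore) return(NULL)
  data.frame(query = queryId, target = targetId, best[, c(
    "qstart", "qend", "tstart", "tend", "strand", "score", "identity",
    "coverage", "matches", "alncols")], row.names = NULL)
}

#' Place cDNAs on a genome with identity and coverage gates
#'
#' Each cDNA is aligned to every scaffold on both strands; all placements
#' with \code{identity >= minIdentity} and \code{coverage >= minCoverage}
#' are reported, and cDNAs with no passing placement are flagged
#' unplaced. The 80\%/50\% defaults are the gates used for calling
#' genotype-specific genes.
#'
#' @param cdnas named \link[Biostrings]{DNAStringSet} (or character).
#' @param genome \linkS4class{GenomeAnnotation} or DNAStringSet.
#' @param minIdentity,minCoverage acceptance gates in (0, 1].
#' @param match,mismatch,gap,seedLength,band,minScore see [alignLocal()].
#' @return A list with \code{placements} (data.frame as in
#'   [alignLocal()]) and \code{unplaced} (character vector of cDNA names).
#' @export
mapCdna <- function(cdnas, genome, minIdentity = 0.80, minCoverage = 0.50,
                    match = 2L, mismatch = -3L, gap = -5L,
                    seedLength = 15L, band = 32L, minScore = 30L) {
  .assertScalarIn(minIdentity, "minIdentity", 1e-9, 1)
  .assertScalarIn(minCoverage, "minCoverage", 0, 1)
  seqs <- if (methods::is(genome, "GenomeAnnotation")) genomeSequences(genome) else genome
  if (length(seqs) == 0L) stop("input error: empty genome", call. = FALSE)
  if (length(cdnas) == 0L) stop("input error: empty cDNA set", call. = FALSE)
  qn <- names(cdnas)
  if (is.null(qn)) qn <- sprintf("cdna%04d", seq_along(cdnas))
  qChar <- toupper(as.character(cdnas))
  hits <- NULL
  for (s in seq_along(seqs)) {
    tChar <- toupper(as.character(seqs[[s]]))
    idx <- .kmerIndex(tChar, seedLength)
    for (i in seq_along(qChar)) {
      r <- .seedExtendAll(qChar[i], tChar, idx, seedLength, match, mismatch,
                          gap, band, TRUE, "dna")
      if (is.null(r)) next
      keep <- r$score >= minScore & r$identity >= minIdentity &
        r$coverage >= minCoverage
      if (!any(keep)) next
      r <- r[keep, , drop = FALSE]
      r$query <- qn[i]
      r$target <- names(seqs)[s]
      hits <- rbind(hits, r)
    }
  }
  cols <- c("query", "target", "qstart", "qend", "tstart", "tend", "strand",
            "score", "identity", "coverage", "matches", "alncols")
  if (is.null(hits)) {
    hits <- data.frame(matrix(nrow = 0, ncol = length(cols),
                              dimnames = list(NULL, cols)))
    hits$query <- character(0)
  } else {
    hits <- hits[order(hits$query, -hits$score), cols]
    rownames(hits) <- NULL
  }
  list(placements = hits, unplaced = setdiff(qn, hits$query))
}

#' All-vs-all homologous gene pair detection
#'
#' For each gene of set A, every gene of set B passing the score,
#' identity and coverage gates is reported with its single best
#' alignment. Content is symmetric in the two sets up to column swap.
#'
#' @param genesA,genesB named \link[Biostrings]{DNAStringSet} of gene
#'   (cDNA) sequences.
#' @param minScore,minIdentity,minCoverage acceptance gates.
#' @param match,mismatch,gap,seedLength,band see [alignLocal()].
#' @return A data.frame with columns \code{geneA}, \code{geneB},
#'   \code{score}, \code{identity}, \code{coverage}, \code{strand}.
#' @export
allVsAllHomologs <- function(genesA, genesB, minScore = 100L,
                             minIdentity = 0.6, minCoverage = 0.5,
                             match = 2L, mismatch = -3L, gap = -5L,
                             seedLength = 15L, band = 32L) {
  if (length(genesA) == 0L || length(genesB) == 0L) {
    stop("input error: empty gene set", call. = FALSE)
  }
  aChar <- toupper(as.character(genesA))
  bChar <- toupper(as.character(genesB))
  nmA <- names(genesA)
  nmB <- names(genesB)
  bIdx <- lapply(bChar, .kmerIndex, k = seedLength)
  # inverted map: k-mer -> B gene indices carrying it
  kmersByGene <- lapply(bIdx, names)
  inv <- split(rep.int(seq_along(bChar), lengths(kmersByGene)),
               unlist(kmersByGene, use.names = FALSE))
  out <- vector("list", length(aChar))
  for (i in seq_along(aChar)) {
    m <- nchar(aChar[i])
    nq <- m - seedLength + 1L
    if (nq < 1L) next
    qk <- substring(aChar[i], seq_len(nq), seq_len(nq) + seedLength - 1L)
    rc <- .revcompChar(aChar[i])
    qkrc <- substring(rc, seq_len(nq), seq_len(nq) + seedLength - 1L)
    candIdx <- unique(unlist(inv[unique(c(qk, qkrc))], use.names = FALSE))
    rows <- lapply(candIdx, function(j) {
      r <- .seedExtendAll(aChar[i], bChar[j], bIdx[[j]], seedLength,
                          match, mismatch, gap, band, TRUE, "dna")
      if (is.null(r)) return(NULL)
      r <- r[order(-r$score), , drop = FALSE][1L, , drop = FALSE]
      if (r$score < minScore || r$identity < minIdentity ||
          r$coverage < minCoverage) return(NULL)
      data.frame(geneA = nmA[i], geneB = nmB[j], score = r$score,
                 identity = r$identity, coverage = r$coverage,
                 strand = r$strand, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(geneA = character(0), geneB = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Organelle-contamination fraction of an assembly
#'
#' Aligns each contaminant sequence to the assembly and reports the total
#' number of assembly bases covered by qualifying alignments (union over
#' hits, no double counting) and their fraction of the assembly length.
#'
#' @param assembly \link[Biostrings]{DNAStringSet} (or
#'   \linkS4class{GenomeAnnotation}).
#' @param contaminants named \link[Biostrings]{DNAStringSet} of organelle
#'   (or other contaminant) sequences.
#' @param minIdentity,minScore,seedLength,band alignment acceptance gates.
#' @return A list with \code{matchedBp} and \code{fraction}.
#' @seealso [contaminationPercent()] for the printed-percentage summary.
#' @export
contaminationFraction <- function(assembly, contaminants, minIdentity = 0.9,
                                  minScore = 50L, seedLength = 15L,
                                  band = 32L) {
  seqs <- if (methods::is(assembly, "GenomeAnnotation")) genomeSequences(assembly) else assembly
  if (length(seqs) == 0L || length(contaminants) == 0L) {
    stop("input error: empty input", call. = FALSE)
  }
  mp <- mapCdna(contaminants, seqs, minIdentity = minIdentity,
                minCoverage = 0, seedLength = seedLength, band = band,
                minScore = minScore)$placements
  matched <- 0L
  if (nrow(mp)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      mp$target, IRanges::IRanges(mp$tstart, mp$tend)))
    matched <- sum(GenomicRanges::width(gr))
  }
  list(matchedBp = matched,
       fraction = matched / sum(Biostrings::width(seqs)))
}

#' Contamination proportion as a printed percentage
#'
#' The two-decimal percentage summary of matched bases over assembly
#' length, e.g. 783287 matched bp over a 4.28 Gb assembly gives 0.02.
#'
#' @param matchedBp total assembly bases covered by contaminant hits.
#' @param totalBp assembly length in bp.
#' @param digits decimals of the printed percentage.
#' @return The percentage, rounded.
#' @examples
#' contaminationPercent(783287, 4.28e9)
#' @export
contaminationPercent <- function(matchedBp, totalBp, digits = 2) {
  .assertScalarIn(matchedBp, "matchedBp", 0)
  .assertScalarIn(totalBp, "totalBp", 1e-9)
  round(matchedBp / totalBp * 100, digits)
}
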