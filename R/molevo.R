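# Molecular-clock computations: Jukes-Cantor corrected distances, the
# Nei-Gojobori (1986) counting method for Ka/Ks, ortholog divergence
# times and LTR retrotransposon insertion ages (T = K / (2 r)).
#
# NG86 conventions used here (and by the pathway-enumeration oracle in
# the test suite): synonymous site fractions count mutations to stop
# codons as non-synonymous; differences are averaged with equal weight
# over all minimal mutational pathways that avoid stop-codon
# intermediates (if every pathway is blocked, all are counted); the
# correction applied to pS and pN is the Jukes-Cantor form.

.molevoCache <- new.env(parent = emptyenv())

.geneticCode <- function() Biostrings::GENETIC_CODE

# per-codon synonymous site count (sum over positions of the fraction of
# the three one-step changes that preserve the amino acid)
.codonSynSites <- function() {
  if (!is.null(.molevoCache$synSites)) return(.molevoCache$synSites)
  gc <- .geneticCode()
  sense <- names(gc)[gc != "*"]
  bases <- DNA_BASES
  syn <- vapply(sense, function(cod) {
    aa <- gc[[cod]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (gc[[alt]] == aa) s <- s + 1 / 3  # stop or aa change: non-syn
      }
    }
    s
  }, 0)
  .molevoCache$synSites <- syn
  syn
}

# synonymous / non-synonymous differences between two sense codons,
# averaged over minimal mutational pathways (stop intermediates skipped)
.codonPairDiffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .molevoCache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- .geneticCode()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- c(sd = 0, nd = 0)
  if (length(pos)) {
    perms <- switch(length(pos),
      list(pos),
      list(pos, pos[2:1]),
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
    paths <- lapply(perms, function(p) {
      cur <- c1
      sd <- 0; nd <- 0; blocked <- FALSE
      for (step in p) {
        nxt <- cur
        substr(nxt, step, step) <- substr(c2, step, step)
        if (gc[[nxt]] == "*" && nxt != c2) blocked <- TRUE
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd, blocked = blocked)
    })
    ok <- !vapply(paths, `[[`, TRUE, "blocked")
    use <- if (any(ok)) paths[ok] else paths
    res <- c(sd = mean(vapply(use, `[[`, 0, "sd")),
             nd = mean(vapply(use, `[[`, 0, "nd")))
  }
  assign(key, res, envir = .molevoCache)
  res
}

#' Jukes-Cantor corrected substitution distance
#'
#' \eqn{K = -\frac{3}{4} \ln(1 - \frac{4p}{3})} for an observed fraction
#' \eqn{p} of differing aligned sites. The correction diverges at
#' \eqn{p = 0.75}; saturated inputs raise an error rather than being
#' clamped.
#'
#' @param p proportion(s) of differing aligned sites, in [0, 0.75).
#' @return Substitutions per site, same length as \code{p}.
#' @examples
#' jc69Distance(0.10)  # 0.10732
#' @export
jc69Distance <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    stop("'p' must be finite and non-negative", call. = FALSE)
  }
  if (any(p >= 0.75)) {
    stop("saturation error: p >= 0.75, Jukes-Cantor correction undefined",
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

.jcOrNA <- function(p) {
  if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Counts synonymous and non-synonymous sites per codon (each position
#' weighted by the fraction of its three one-step changes that are
#' synonymous), averages differences over all minimal mutational
#' pathways between differing codons (pathways through stop codons
#' excluded), and applies the Jukes-Cantor-style correction to the raw
#' proportions pS and pN.
#'
#' @param seqA,seqB equal-length in-frame coding sequences over ACGT
#'   (character or XString); length divisible by 3; no in-frame stops
#'   (a shared terminal stop codon is trimmed).
#' @return A list: \code{ka}, \code{ks}, \code{ratio} (Ka/Ks, NA when Ks
#'   is 0), raw proportions \code{pn}, \code{ps}, counts \code{sd},
#'   \code{nd}, site totals \code{S}, \code{N}, and \code{flags}
#'   (character; "saturated" and/or "ks_zero").
#' @examples
#' ng86KaKs("GGAGGA", "GGGGGA")  # one synonymous difference
#' @export
ng86KaKs <- function(seqA, seqB) {
  a <- .asSeqChar(seqA)
  b <- .asSeqChar(seqB)
  if (nchar(a) != nchar(b)) stop("sequences must be equal length", call. = FALSE)
  if (nchar(a) %% 3L != 0L) stop("length must be divisible by 3", call. = FALSE)
  if (nchar(a) < 3L) stop("need at least one codon", call. = FALSE)
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) {
    stop("input error: sequences must be over {A,C,G,T}", call. = FALSE)
  }
  n3 <- seq(1L, nchar(a), by = 3L)
  codA <- substring(a, n3, n3 + 2L)
  codB <- substring(b, n3, n3 + 2L)
  gc <- .geneticCode()
  stopA <- gc[codA] == "*"
  stopB <- gc[codB] == "*"
  nc <- length(codA)
  if ((any(stopA) || any(stopB))) {
    terminal <- stopA[nc] && stopB[nc] && !any(stopA[-nc]) && !any(stopB[-nc])
    if (!terminal) {
      stop("input error: in-frame stop codon", call. = FALSE)
    }
    codA <- codA[-nc]; codB <- codB[-nc]
  }
  syn <- .codonSynSites()
  S <- (sum(syn[codA]) + sum(syn[codB])) / 2
  N <- 3 * length(codA) - S
  diffs <- vapply(which(codA != codB), function(i)
    .codonPairDiffs(codA[i], codB[i]), c(sd = 0, nd = 0))
  sd <- if (length(diffs)) sum(diffs["sd", ]) else 0
  nd <- if (length(diffs)) sum(diffs["nd", ]) else 0
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  ks <- .jcOrNA(ps)
  ka <- .jcOrNA(pn)
  flags <- character(0)
  if (is.na(ks) || is.na(ka)) flags <- c(flags, "saturated")
  ratio <- NA_real_
  if (!is.na(ks) && !is.na(ka)) {
    if (ks == 0) flags <- c(flags, "ks_zero") else ratio <- ka / ks
  }
  list(ka = ka, ks = ks, ratio = ratio, pn = pn, ps = ps, sd = sd, nd = nd,
       S = S, N = N, flags = flags)
}

#' Divergence time from mean synonymous divergence
#'
#' \eqn{T = Ks / (2 r)}, reported in MYA, with the universal grass
#' substitution rate \eqn{r = 6.5 \times 10^{-9}} per site per year as
#' default.
#'
#' @param meanKs mean synonymous substitutions per synonymous site.
#' @param rate substitutions per site per year.
#' @return Time in MYA.
#' @examples
#' divergenceTime(0.13)  # 10 MYA
#' @export
divergenceTime <- function(meanKs, rate = 6.5e-9) {
  if (!is.numeric(meanKs) || any(meanKs < 0)) {
    stop("'meanKs' must be non-negative", call. = FALSE)
  }
  .assertScalarIn(rate, "rate", 1e-300)
  meanKs / (2 * rate) / 1e6
}

#' LTR retrotransposon insertion time
#'
#' Globally aligns the two LTRs of an element, takes the p-distance over
#' aligned non-gap columns, corrects it with [jc69Distance()] and dates
#' the insertion as \eqn{T = K / (2 r)}. Both the raw p-distance and the
#' corrected K are returned. Saturated pairs are flagged, not clamped.
#'
#' @param ltr5,ltr3 the element's two LTR sequences.
#' @param rate LTR clock, substitutions per site per year (default
#'   \eqn{1.3 \times 10^{-8}}).
#' @return A list: \code{p}, \code{k}, \code{rate}, \code{timeMya}
#'   (NA when saturated), \code{flags}.
#' @export
ltrInsertionTime <- function(ltr5, ltr3, rate = 1.3e-8) {
  .assertScalarIn(rate, "rate", 1e-300)
  a <- .asSeqChar(ltr5)
  b <- .asSeqChar(ltr3)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 4, gapExtension = 1)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  p <- if (nm + nmm > 0) nmm / (nm + nmm) else 0
  k <- .jcOrNA(p)
  flags <- character(0)
  if (is.na(k)) flags <- "saturated"
  list(p = p, k = k, rate = rate,
       timeMya = if (is.na(k)) NA_real_ else k / (2 * rate) / 1e6,
       flags = flags)
}

#' Date a set of LTR element pairs
#'
#' @param seqs \link[Biostrings]{DNAStringSet} of paired LTRs named
#'   \code{<element>_5p} / \code{<element>_3p} (as emitted by
#'   [simulateLtrPairs()]).
#' @param rate clock rate, substitutions per site per year.
#' @return data.frame: \code{element}, \code{p}, \code{k},
#'   \code{timeMya}, \code{saturated}.
#' @export
ltrAgeTable <- function(seqs, rate = 1.3e-8) {
  nm <- names(seqs)
  el5 <- sub("_5p$", "", nm[grepl("_5p$", nm)])
  el3 <- sub("_3p$", "", nm[grepl("_3p$", nm)])
  elements <- intersect(el5, el3)
  if (!length(elements)) stop("no *_5p/*_3p sequence pairs found", call. = FALSE)
  rows <- lapply(elements, function(e) {
    r <- ltrInsertionTime(seqs[[paste0(e, "_5p")]],
                          seqs[[paste0(e, "_3p")]], rate)
    data.frame(element = e, p = r$p, k = r$k, timeMya = r$timeMya,
               saturated = length(r$flags) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ka/Ks over an ortholog pair table
#'
#' Applies [ng86KaKs()] to each ortholog cDNA pair of equal length
#' (pairs of unequal length are skipped with a flag; indel-aware codon
#' alignment is out of scope of this package).
#'
#' @param cdnaA,cdnaB named \link[Biostrings]{DNAStringSet}.
#' @param pairs data.frame with columns \code{geneA}, \code{geneB}.
#' @return data.frame: \code{geneA}, \code{geneB}, \code{ka}, \code{ks},
#'   \code{ratio}, \code{flags} (comma-collapsed).
#' @export
kaksTable <- function(cdnaA, cdnaB, pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- cdnaA[[pairs$geneA[i]]]
    b <- cdnaB[[pairs$geneB[i]]]
    if (length(a) != length(b) || length(a) %% 3L != 0L) {
      return(data.frame(geneA = pairs$geneA[i], geneB = pairs$geneB[i],
                        ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                        flags = "length_mismatch", stringsAsFactors = FALSE))
    }
    r <- tryCatch(ng86KaKs(a, b), error = function(e) NULL)
    if (is.null(r)) {
      return(data.frame(geneA = pairs$geneA[i], geneB = pairs$geneB[i],
                        ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                        flags = "invalid_codons", stringsAsFactors = FALSE))
    }
    data.frame(geneA = pairs$geneA[i], geneB = pairs$geneB[i], ka = r$ka,
               ks = r$ks, ratio = r$ratio,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
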