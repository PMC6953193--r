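# Tissue-specific expression classification: median-of-ratios
# normalization and a transparent negative-binomial Wald test with
# method-of-moments dispersion. A gene is tissue-specific and highly
# expressed iff its normalized mean in one tissue is at least
# foldThreshold times that of EVERY other tissue with BH-adjusted
# p <= padjThreshold in every comparison; the fold gate makes the call
# exclusive to at most one tissue.

#' Median-of-ratios size factors
#'
#' factor_j = median over genes of count_gj / geometric-mean_g, computed
#' over genes with a nonzero geometric mean.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return Named numeric vector of per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(NULL, c("a", "b")))
#' medianRatioSizeFactors(m)
#' @export
medianRatioSizeFactors <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use)) {
    stop("no gene with nonzero counts in all samples", call. = FALSE)
  }
  apply(counts[use, , drop = FALSE], 2L,
        function(cnt) exp(median(log(cnt) - logGeo[use])))
}

.tissueDesign <- function(counts, tissues) {
  if (is.null(names(tissues))) {
    if (length(tissues) != ncol(counts)) {
      stop("'tissues' must map every sample", call. = FALSE)
    }
    names(tissues) <- colnames(counts)
  }
  tissues <- tissues[colnames(counts)]
  if (anyNA(tissues)) stop("'tissues' must map every sample", call. = FALSE)
  if (any(table(tissues) < 2L)) {
    stop("every tissue needs >= 2 replicates", call. = FALSE)
  }
  if (length(unique(tissues)) < 2L) stop("need >= 2 tissues", call. = FALSE)
  tissues
}

#' Tissue-specific, highly expressed gene calls
#'
#' Normalizes the matrix by [medianRatioSizeFactors()], estimates one
#' method-of-moments NB dispersion per gene from within-tissue
#' replicates, and Wald-tests the log fold change of every
#' (gene, tissue, other tissue) combination. P-values are BH-adjusted
#' across the whole family. A gene is called for a tissue iff its
#' normalized mean there is at least \code{foldThreshold} times the mean
#' of every other tissue and every comparison has adjusted
#' p <= \code{padjThreshold}. At most one tissue can satisfy the fold
#' gate.
#'
#' @param counts genes x samples integer matrix (or a
#'   SummarizedExperiment with a \code{tissue} column in colData).
#' @param tissues named character, sample to tissue (ignored for a
#'   SummarizedExperiment input).
#' @param foldThreshold minimum normalized-mean ratio vs every other
#'   tissue (2 = log2FC >= 1).
#' @param padjThreshold maximum BH-adjusted p in every comparison.
#' @return data.frame, one row per gene: \code{gene}, \code{tissue} (NA
#'   when not specific), \code{minLog2fcVsOthers},
#'   \code{maxPadjVsOthers}.
#' @export
tissueSpecific <- function(counts, tissues, foldThreshold = 2,
                           padjThreshold = 0.01) {
  if (methods::is(counts, "SummarizedExperiment")) {
    se <- counts
    counts <- SummarizedExperiment::assay(se)
    tissues <- stats::setNames(as.character(se$tissue), colnames(counts))
  }
  .assertScalarIn(foldThreshold, "foldThreshold", 1)
  .assertScalarIn(padjThreshold, "padjThreshold", 0, 1)
  tissues <- .tissueDesign(counts, tissues)
  tl <- unique(tissues)
  sf <- medianRatioSizeFactors(counts)
  norm <- sweep(counts, 2L, sf, "/")

  nG <- nrow(counts)
  means <- vapply(tl, function(t)
    rowMeans(norm[, tissues == t, drop = FALSE]), numeric(nG))
  vars <- vapply(tl, function(t)
    apply(norm[, tissues == t, drop = FALSE], 1L, var), numeric(nG))
  nrep <- vapply(tl, function(t) sum(tissues == t), 0L)

  # pooled method-of-moments dispersion per gene: var = mu + alpha mu^2.
  # With few replicates the per-gene estimate is dominated by chi-square
  # noise, so it is squeezed toward the across-gene median (prior weight
  # priorDf, residual df = samples - tissues), the usual moderation for
  # small designs.
  alpha <- pmax(0, rowSums(vars - means) / rowSums(means^2))
  residDf <- length(tissues) - length(tl)
  priorDf <- 20
  alphaMid <- median(alpha)
  alpha <- (residDf * alpha + priorDf * alphaMid) / (residDf + priorDf)

  eps <- 1e-8
  # Wald z for each ordered tissue pair, delta-method variance of log-mean
  logVar <- sweep(1 / pmax(means, eps) + alpha, 2L, nrep, "/")
  nPairs <- length(tl) * (length(tl) - 1L)
  pmat <- matrix(NA_real_, nG, nPairs)
  lfcmat <- matrix(NA_real_, nG, nPairs)
  colPair <- character(nPairs)
  cc <- 0L
  for (t in seq_along(tl)) {
    for (u in seq_along(tl)) {
      if (t == u) next
      cc <- cc + 1L
      colPair[cc] <- paste(tl[t], tl[u], sep = "|")
      lfc <- log2(pmax(means[, t], eps)) - log2(pmax(means[, u], eps))
      z <- (log(pmax(means[, t], eps)) - log(pmax(means[, u], eps))) /
        sqrt(logVar[, t] + logVar[, u])
      pmat[, cc] <- 2 * pnorm(-abs(z))
      lfcmat[, cc] <- lfc
    }
  }
  padj <- matrix(p.adjust(pmat, method = "BH"), nG, nPairs)

  out <- data.frame(gene = rownames(counts), tissue = NA_character_,
                    minLog2fcVsOthers = NA_real_,
                    maxPadjVsOthers = NA_real_, stringsAsFactors = FALSE)
  log2fold <- log2(foldThreshold)
  for (t in seq_along(tl)) {
    cols <- which(startsWith(colPair, paste0(tl[t], "|")))
    minLfc <- apply(lfcmat[, cols, drop = FALSE], 1L, min)
    maxP <- apply(padj[, cols, drop = FALSE], 1L, max)
    hit <- minLfc >= log2fold & maxP <= padjThreshold
    out$tissue[hit] <- tl[t]
    out$minLog2fcVsOthers[hit] <- minLfc[hit]
    out$maxPadjVsOthers[hit] <- maxP[hit]
  }
  out
}
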