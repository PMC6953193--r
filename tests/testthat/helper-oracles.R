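# Independent oracles and small fixture builders used across the suite.
# Each oracle is written directly from first principles (full dynamic
# programming, exhaustive enumeration) and never calls the code path it
# checks.

rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutateSeq <- function(s, nMut) {
  pos <- sample(nchar(s), nMut)
  for (p in pos) {
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1L)
  }
  s
}

# optimal local alignment score with linear gaps: Biostrings full DP
swOracleScore <- function(q, t, match = 2, mismatch = -3, gap = -5) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, t, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch),
    gapOpening = 0, gapExtension = abs(gap)))
}

swOracleAlign <- function(q, t, match = 2, mismatch = -3, gap = -5) {
  Biostrings::pairwiseAlignment(
    q, t, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch),
    gapOpening = 0, gapExtension = abs(gap))
}

# ---- NG86 oracle: recursive pathway enumeration from the genetic code ----

ng86OracleSites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# every complete mutational pathway c1 -> c2, one step per differing
# position, as rows (sd, nd, blocked)
ng86OraclePaths <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  recurse <- function(cur, blocked) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(d)) return(list(c(sd = 0, nd = 0, blocked = blocked)))
    out <- list()
    for (pos in d) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      stepBlocked <- blocked || (gc[[nxt]] == "*" && nxt != c2)
      syn <- gc[[cur]] == gc[[nxt]]
      for (tail in recurse(nxt, stepBlocked)) {
        tail["sd"] <- tail["sd"] + as.numeric(syn)
        tail["nd"] <- tail["nd"] + as.numeric(!syn)
        out[[length(out) + 1L]] <- tail
      }
    }
    out
  }
  do.call(rbind, recurse(c1, FALSE))
}

ng86OracleDiffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  p <- ng86OraclePaths(c1, c2)
  ok <- p[, "blocked"] == 0
  use <- if (any(ok)) p[ok, , drop = FALSE] else p
  c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
}

ng86Oracle <- function(a, b) {
  n3 <- seq(1L, nchar(a), by = 3L)
  codA <- substring(a, n3, n3 + 2L)
  codB <- substring(b, n3, n3 + 2L)
  S <- (sum(vapply(codA, ng86OracleSites, 0)) +
        sum(vapply(codB, ng86OracleSites, 0))) / 2
  N <- 3 * length(codA) - S
  d <- rowSums(vapply(seq_along(codA), function(i)
    ng86OracleDiffs(codA[i], codB[i]), c(sd = 0, nd = 0)))
  ps <- d[["sd"]] / S
  pn <- d[["nd"]] / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(ks = jc(ps), ka = jc(pn),
       sd = d[["sd"]], nd = d[["nd"]], S = S, N = N)
}

# random coding sequence of sense codons (no in-frame stop)
rndCoding <- function(nCodon) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], nCodon, TRUE), collapse = "")
}

# ---- synteny oracle: exhaustive chain enumeration ----

# all valid chains (index vectors into the pair table) for one
# orientation, grown by depth-first extension under the gap rules
enumChains <- function(a, b, maxGap, orientation) {
  n <- length(a)
  succ <- lapply(seq_len(n), function(i) {
    ok <- a > a[i] & (a - a[i] - 1L) < maxGap
    ok <- ok & if (orientation == "same") {
      b > b[i] & (b - b[i] - 1L) < maxGap
    } else {
      b < b[i] & (b[i] - b - 1L) < maxGap
    }
    which(ok)
  })
  chains <- list()
  grow <- function(chain) {
    chains[[length(chains) + 1L]] <<- chain
    for (j in succ[[chain[length(chain)]]]) grow(c(chain, j))
  }
  for (i in seq_len(n)) grow(i)
  chains
}

# comparator identical in spirit to the block caller's documented
# tie-break: longest, then smallest summed gap, then leftmost on A, then
# leftmost on B, then same orientation, then lexicographic ordinals
chainKey <- function(a, b, chain, orientation) {
  gA <- diff(a[chain]) - 1L
  gB <- abs(diff(b[chain])) - 1L
  list(n = length(chain), sumGap = sum(gA) + sum(gB),
       startA = a[chain[1L]], startB = b[chain[1L]],
       orientation = orientation,
       lex = as.vector(rbind(a[chain], b[chain])))
}

keyBetter <- function(x, y) {
  if (is.null(y)) return(TRUE)
  if (x$n != y$n) return(x$n > y$n)
  if (x$sumGap != y$sumGap) return(x$sumGap < y$sumGap)
  if (x$startA != y$startA) return(x$startA < y$startA)
  if (x$startB != y$startB) return(x$startB < y$startB)
  if (x$orientation != y$orientation) return(x$orientation == "same")
  cmp <- x$lex - y$lex
  nz <- which(cmp != 0)
  if (length(nz)) return(cmp[nz[1L]] < 0)
  FALSE
}

# exhaustive analogue of callBlocks for a single sequence combination
oracleBlocks <- function(pairs, minBlockGenes, maxGap,
                         allowInversions = TRUE) {
  avail <- pairs
  blocks <- list()
  repeat {
    if (nrow(avail) < minBlockGenes) break
    best <- NULL
    bestChain <- NULL
    bestOri <- NULL
    for (ori in if (allowInversions) c("same", "inverted") else "same") {
      for (chain in enumChains(avail$aOrd, avail$bOrd, maxGap, ori)) {
        k <- chainKey(avail$aOrd, avail$bOrd, chain, ori)
        if (keyBetter(k, best)) {
          best <- k; bestChain <- chain; bestOri <- ori
        }
      }
    }
    if (is.null(best) || best$n < minBlockGenes) break
    mem <- avail[bestChain, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <-
      list(orientation = bestOri, members = mem)
    avail <- avail[!(avail$geneA %in% mem$geneA |
                     avail$geneB %in% mem$geneB), , drop = FALSE]
  }
  blocks
}

# random homolog-pair instance on one sequence combination: a mix of
# collinear stretches and scattered pairs, with gene orders large enough
# to leave gaps
rndPairInstance <- function(nPairs, nGenesA = 40L, nGenesB = 40L,
                            collinearFrac = 0.5) {
  nCol <- round(nPairs * collinearFrac)
  aOrd <- sample.int(nGenesA, nPairs) - 1L
  bAll <- sample.int(nGenesB, nPairs) - 1L
  bOrd <- bAll
  if (nCol > 1L) {
    o <- order(aOrd[seq_len(nCol)])
    bOrd[seq_len(nCol)[o]] <- sort(bAll[seq_len(nCol)])
  }
  data.frame(geneA = sprintf("a%03d", seq_len(nPairs)),
             geneB = sprintf("b%03d", seq_len(nPairs)),
             aOrd = aOrd, bOrd = bOrd, stringsAsFactors = FALSE)
}

# order indexes for a pair instance (ordinals become coordinates)
ordersFromInstance <- function(inst, nGenesA = 40L, nGenesB = 40L) {
  mkOrder <- function(genes, ords, n, seqname) {
    allOrd <- seq_len(n) - 1L
    gene <- sprintf("%s_fill%03d", seqname, allOrd)
    gene[ords + 1L] <- genes
    data.frame(gene = gene, seq = seqname, ordinal = allOrd, strand = "+",
               start = allOrd * 100L + 1L, end = allOrd * 100L + 50L,
               stringsAsFactors = FALSE)
  }
  list(orderA = mkOrder(inst$geneA, inst$aOrd, nGenesA, "sA"),
       orderB = mkOrder(inst$geneB, inst$bOrd, nGenesB, "sB"))
}

# compact canonical form of a block set for comparison
blockSignature <- function(blocks) {
  if (is.data.frame(blocks)) {
    lapply(seq_len(nrow(blocks)), function(i) {
      m <- blocks$members[[i]]
      paste(blocks$orientation[i],
            paste(m$geneA, m$geneB, sep = ":", collapse = ","))
    })
  } else {
    lapply(blocks, function(b) {
      paste(b$orientation,
            paste(b$members$geneA, b$members$geneB, sep = ":",
                  collapse = ","))
    })
  }
}

# small two-genotype simulation used by several suites
smallSimSpec <- function(seed = 101, ...) {
  simulationSpec(seed = seed, nScaffolds = 1L, nGenes = 20L,
                 scaffoldLength = 60000L, nSpecificA = 3L, nSpecificB = 3L,
                 periStart = 15000, periEnd = 30000, ...)
}
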