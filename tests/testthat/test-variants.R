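test_that("read placement honours the substitution budget and tie rule", {
  set.seed(41)
  g <- rndDna(5000)
  # duplicate a segment so reads from it are ambiguous
  g <- paste0(g, substr(g, 1001, 1100))
  ref <- Biostrings::DNAStringSet(c(chr = g))

  exact <- substr(g, 2001, 2100)
  two <- mutateSeq(exact, 2)
  three <- mutateSeq(exact, 3)
  dup <- substr(g, 1001, 1100)
  reads <- Biostrings::DNAStringSet(c(exact = exact, two = two,
                                      three = three, dup = dup))
  pl <- mapReads(reads, ref, maxSubstitutions = 2)
  expect_setequal(pl$readId, c("exact", "two"))
  expect_equal(pl$start[pl$readId == "exact"], 2001L)
  expect_equal(pl$nMismatches[pl$readId == "exact"], 0L)
  expect_equal(pl$nMismatches[pl$readId == "two"], 2L)

  # reverse-strand reads are placed in forward coordinates
  rcRead <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, 3001, 3100))))
  pl2 <- mapReads(Biostrings::DNAStringSet(c(rc = rcRead)), ref)
  expect_equal(pl2$start, 3001L)
  expect_equal(pl2$strand, "-")
})

test_that("pileup SNV calling applies the depth and allele-fraction gates", {
  set.seed(43)
  g <- rndDna(1000)
  ref <- Biostrings::DNAStringSet(c(chr = g))
  mkReads <- function(start, n, altAt = NA, width = 100L) {
    s <- substr(g, start, start + width - 1L)
    if (!is.na(altAt)) {
      p <- altAt - start + 1L
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, p, p))[1]
    }
    setNames(rep(s, n), sprintf("r_%d_%d", start, seq_len(n)))
  }
  # variant supported by 5 concordant reads: called; by 3: not called
  reads <- Biostrings::DNAStringSet(c(mkReads(101, 5, altAt = 150),
                                      mkReads(501, 3, altAt = 550)))
  pl <- mapReads(reads, ref)
  snvs <- callSnvs(pl, ref, minDepth = 4, minAltFraction = 0.9)
  expect_equal(GenomicRanges::start(snvs), 150L)
  expect_equal(snvs$depth, 5L)
  expect_equal(snvs$altFraction, 1)
  expect_equal(snvs$ref, substr(g, 150, 150))

  # no planted variant and no errors: nothing is ever called
  clean <- Biostrings::DNAStringSet(mkReads(301, 10))
  expect_length(callSnvs(mapReads(clean, ref), ref), 0L)
})

test_that("raising min depth never adds SNV calls", {
  spec <- smallSimSpec(seed = 311, readDepth = 8)
  sim <- simulateGenomePair(spec)
  reads <- simulateReads(sim$genomeA, spec, "readsA")
  pl <- mapReads(reads, sim$genomeB)
  s4 <- callSnvs(pl, sim$genomeB, minDepth = 4)
  s6 <- callSnvs(pl, sim$genomeB, minDepth = 6)
  expect_true(all(paste(GenomicRanges::seqnames(s6),
                        GenomicRanges::start(s6)) %in%
                  paste(GenomicRanges::seqnames(s4),
                        GenomicRanges::start(s4))))
})

test_that("planted SNVs are recovered exactly where the pileup is deep enough", {
  spec <- smallSimSpec(seed = 313, readDepth = 15, snvRate = 0.002)
  sim <- simulateGenomePair(spec)
  reads <- simulateReads(sim$genomeA, spec, "readsA")
  pl <- mapReads(reads, sim$genomeB)
  snvs <- callSnvs(pl, sim$genomeB)
  tr <- truthSnv(sim$truth)
  # precision: every call is a planted difference
  expect_true(all(GenomicRanges::start(snvs) %in% tr$posB))
  # reference is genotype B, reads are genotype A: the called alt allele
  # is A's base (truth ref) and the called ref is B's base (truth alt)
  m <- match(GenomicRanges::start(snvs), tr$posB)
  expect_identical(snvs$alt, tr$ref[m])
  expect_identical(snvs$ref, tr$alt[m])
  # recall is perfect on sites with pileup depth >= 4
  cov <- depthProfile(pl, sim$genomeB)[[1]]
  deep <- tr$posB[as.integer(cov[tr$posB]) >= 4]
  expect_true(all(deep %in% GenomicRanges::start(snvs)))
})

test_that("window densities tile scaffolds, keep totals and obey 1-based edges", {
  sl <- c(chrA = 2.5e7, chrB = 7e6)
  none <- windowDensity(GenomicRanges::GRanges(), sl, window = 1e7)
  expect_equal(sum(none$count), 0L)
  expect_equal(as.integer(table(GenomicRanges::seqnames(none))), c(3L, 1L))
  expect_true(none$partial[3] && none$partial[4])
  expect_equal(GenomicRanges::width(none)[1:2], rep(1e7, 2))

  # a site at exactly position 10,000,000 belongs to the first window
  snvs <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(c(1e7, 1e7 + 1, 2.1e7), width = 1),
    ref = "A", alt = "C", depth = 5L, altFraction = 1)
  wd <- windowDensity(snvs, sl, window = 1e7)
  expect_equal(wd$count[as.logical(GenomicRanges::seqnames(wd) == "chrA")],
               c(1L, 1L, 1L))
  expect_equal(sum(wd$count), length(snvs))
  expect_error(windowDensity(GenomicRanges::GRanges("chrA",
    IRanges::IRanges(3e7, width = 1)), sl), "bounds")
})

test_that("windowed densities recover the planted pericentromeric elevation", {
  spec <- simulationSpec(seed = 401, nScaffolds = 1L, nGenes = 30L,
                         scaffoldLength = 500000L, nSpecificA = 0L,
                         nSpecificB = 0L, snvRate = 0.002,
                         periStart = 150000, periEnd = 350000,
                         periMultiplier = 3, readDepth = 10)
  sim <- simulateGenomePair(spec)
  reads <- simulateReads(sim$genomeA, spec, "readsA")
  snvs <- callSnvs(mapReads(reads, sim$genomeB), sim$genomeB)
  wd <- windowDensity(snvs, sim$genomeB, window = 25000)
  dr <- densityRatio(wd, 150000, 350000)
  se <- dr$ratio * sqrt(1 / dr$countIn + 1 / dr$countOut)
  expect_lt(abs(dr$ratio - 3), 3 * se + 0.3)
})

test_that("gene coverage fractions reflect read placement exactly", {
  set.seed(47)
  g <- rndDna(2000)
  gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(501, 700),
                               strand = "+", gene_id = "g1")
  genome <- GenomeAnnotation(Biostrings::DNAStringSet(c(chr = g)), gr)
  # reads tile exactly half of the gene span
  reads <- Biostrings::DNAStringSet(setNames(
    substring(g, c(501, 551), c(550, 600)), c("r1", "r2")))
  pl <- mapReads(reads, genome)
  cv <- geneCoverage(pl, genome)
  expect_equal(cv$coveredBp, 100L)
  expect_equal(cv$coveredFraction, 0.5)
})
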