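test_that("with no specific genes and zero SNV rate the genotypes are identical", {
  spec <- simulationSpec(seed = 1, nScaffolds = 1L, nGenes = 10L,
                         scaffoldLength = 30000L, nSpecificA = 0L,
                         nSpecificB = 0L, snvRate = 0)
  sim <- simulateGenomePair(spec)
  expect_identical(as.character(genomeSequences(sim$genomeA)),
                   as.character(genomeSequences(sim$genomeB)))
  expect_identical(unname(as.character(cdnaSeqs(sim$genomeA))),
                   unname(as.character(cdnaSeqs(sim$genomeB))))
  expect_equal(nrow(truthOrthologs(sim$truth)), 10L)
  expect_equal(nrow(truthSnv(sim$truth)), 0L)
})

test_that("planted specific genes are deleted/inserted exactly as recorded", {
  spec <- simulationSpec(seed = 7, nScaffolds = 2L, nGenes = 20L,
                         scaffoldLength = 40000L, nSpecificA = 5L,
                         nSpecificB = 3L)
  sim <- simulateGenomePair(spec)
  tr <- sim$truth
  expect_length(truthSpecificA(tr), 5L)
  expect_length(truthSpecificB(tr), 3L)
  # conservation: |genes(B)| = n - nSpecificA + nSpecificB
  expect_equal(length(geneModels(sim$genomeB)), 20L - 5L + 3L)
  expect_equal(length(geneModels(sim$genomeA)), 20L)
  # A-specific ids exist in A but have no B ortholog
  om <- truthOrthologs(tr)
  expect_true(all(truthSpecificA(tr) %in% geneModels(sim$genomeA)$gene_id))
  expect_false(any(truthSpecificA(tr) %in% om$geneA))
  expect_false(any(truthSpecificB(tr) %in% om$geneB))
  # every truth identifier exists in the emitted annotations
  expect_true(all(om$geneA %in% geneModels(sim$genomeA)$gene_id))
  expect_true(all(om$geneB %in% geneModels(sim$genomeB)$gene_id))
  # gene intervals do not overlap within a scaffold
  for (g in list(geneModels(sim$genomeA), geneModels(sim$genomeB))) {
    hits <- GenomicRanges::findOverlaps(g, g, ignore.strand = TRUE)
    expect_equal(length(hits), length(g))  # only self-hits
  }
})

test_that("planted SNV truth matches both genomes and regional rates", {
  spec <- simulationSpec(seed = 13, nScaffolds = 1L, nGenes = 30L,
                         scaffoldLength = 400000L, nSpecificA = 4L,
                         nSpecificB = 4L, snvRate = 0.01,
                         periStart = 100000, periEnd = 200000,
                         periMultiplier = 3)
  sim <- simulateGenomePair(spec)
  s <- truthSnv(sim$truth)
  a <- as.character(genomeSequences(sim$genomeA)[[1]])
  b <- as.character(genomeSequences(sim$genomeB)[[1]])
  expect_true(all(substring(a, s$posA, s$posA) == s$ref))
  expect_true(all(substring(b, s$posB, s$posB) == s$alt))
  expect_true(all(s$ref != s$alt))
  expect_false(is.unsorted(s$posA, strictly = TRUE))
  # realized counts within 3 binomial SDs of expectation per region
  periLen <- 100001
  inPeri <- s$posA >= 100000 & s$posA <= 200000
  expPeri <- periLen * 0.03
  expArm <- (400000 - periLen) * 0.01
  # deleted spans carry no SNVs; shrink arm expectation accordingly
  delBp <- sum(GenomicRanges::width(
    geneModels(sim$genomeA)[truthSpecificA(sim$truth)]))
  expect_lt(abs(sum(inPeri) - expPeri), 3 * sqrt(expPeri) + 0.1 * delBp)
  expect_lt(abs(sum(!inPeri) - expArm), 3 * sqrt(expArm) + 0.1 * delBp)
})

test_that("identical specs give byte-identical FASTA/GFF3/FASTQ/TSV outputs", {
  spec <- simulationSpec(seed = 5, nScaffolds = 1L, nGenes = 8L,
                         scaffoldLength = 25000L, nSpecificA = 1L,
                         nSpecificB = 1L, nLtrPairs = 2L, ltrLength = 2000L,
                         readDepth = 2, readErrorRate = 0.01)
  paths <- lapply(1:2, function(run) {
    d <- tempfile(sprintf("simrun%d", run))
    dir.create(d)
    sim <- simulateGenomePair(spec)
    writeGenome(sim$genomeB, file.path(d, "b.fa"), file.path(d, "b.gff3"))
    writeFastqFile(simulateReads(sim$genomeA, spec), file.path(d, "r.fastq"))
    ltr <- simulateLtrPairs(spec)
    Biostrings::writeXStringSet(ltr$seqs, file.path(d, "ltr.fa"))
    cnt <- simulateCounts(spec)
    writeCountsTsv(cnt$counts, cnt$tissueMap, file.path(d, "c.tsv"),
                   file.path(d, "t.tsv"))
    d
  })
  for (f in c("b.fa", "b.gff3", "r.fastq", "ltr.fa", "c.tsv", "t.tsv")) {
    expect_identical(readBin(file.path(paths[[1]], f), "raw", 1e7),
                     readBin(file.path(paths[[2]], f), "raw", 1e7),
                     label = f)
  }
})

test_that("read simulation honours depth, exactness and bounds", {
  spec <- simulationSpec(seed = 3, nScaffolds = 1L, nGenes = 10L,
                         scaffoldLength = 100000L, readDepth = 10,
                         readLength = 100L, readErrorRate = 0)
  sim <- simulateGenomePair(spec)
  reads <- simulateReads(sim$genomeA, spec)
  expect_equal(length(reads), 10000L)  # depth * length / readLength
  # with zero error rate every read is an exact substring of its scaffold
  g <- genomeSequences(sim$genomeA)[[1]]
  meta <- do.call(rbind, strsplit(names(reads), "|", fixed = TRUE))
  pos <- as.integer(meta[, 2])
  idx <- sample(length(reads), 200)
  win <- as.character(Biostrings::DNAStringSet(
    Biostrings::Views(g, start = pos[idx], width = 100L)))
  rd <- reads[idx]
  neg <- meta[idx, 3] == "-"
  rd[neg] <- Biostrings::reverseComplement(rd[neg])
  expect_identical(as.character(rd), setNames(win, names(rd)))
  # depth must be positive and reads must fit the scaffold
  expect_error(simulateReads(sim$genomeA,
                             simulationSpec(readDepth = 10,
                                            readLength = 300000L)),
               "scaffold")
})

test_that("LTR pairs diverge to the planted clock expectation", {
  spec0 <- simulationSpec(seed = 2, nLtrPairs = 3L, ltrAges = 0,
                          ltrLength = 5000L)
  lt0 <- simulateLtrPairs(spec0)
  expect_identical(as.character(lt0$seqs[["ltr001_5p"]]),
                   as.character(lt0$seqs[["ltr001_3p"]]))
  spec1 <- simulationSpec(seed = 2, nLtrPairs = 8L, ltrAges = 1,
                          ltrLength = 10000L)
  lt1 <- simulateLtrPairs(spec1)
  k <- 2 * 1.3e-8 * 1e6          # expected substitutions per site at 1 MYA
  p <- 0.75 * (1 - exp(-4 * k / 3))
  d <- vapply(1:8, function(i) {
    sum(charToRaw(as.character(lt1$seqs[[2 * i - 1]])) !=
        charToRaw(as.character(lt1$seqs[[2 * i]])))
  }, 0L)
  expect_true(all(abs(d - 10000 * p) < 3 * sqrt(10000 * p * (1 - p))))
  # saturated ages are refused, not clamped
  expect_error(simulateLtrPairs(simulationSpec(ltrAges = 1000)),
               "saturation")
})

test_that("count simulation plants fold changes in exactly one tissue", {
  expect_equal(nrow(simulateCounts(simulationSpec(foldChange = 1))$truth), 0L)
  spec <- simulationSpec(seed = 11, nGenes = 300L, foldChange = 4,
                         nbDispersion = 0.05)
  cnt <- simulateCounts(spec)
  expect_equal(dim(cnt$counts), c(300L, 12L))
  expect_true(all(cnt$counts >= 0))
  tr <- cnt$truth
  expect_gt(nrow(tr), 0L)
  expect_false(anyDuplicated(tr$gene) > 0)
  ratios <- vapply(seq_len(nrow(tr)), function(i) {
    inT <- cnt$tissueMap[colnames(cnt$counts)] == tr$tissue[i]
    mean(cnt$counts[tr$gene[i], inT]) / mean(cnt$counts[tr$gene[i], !inT])
  }, 0)
  expect_true(all(ratios > 2))
  expect_lt(abs(mean(ratios) - 4), 1)
  expect_error(simulateCounts(simulationSpec(tissues = c("a", "b"),
                                             repsPerTissue = 1L)),
               "replicates")
})
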