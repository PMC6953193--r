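test_that("cross-placement splits genes into placed and candidate", {
  set.seed(53)
  genomeB <- Biostrings::DNAStringSet(c(s1 = rndDna(30000)))
  present <- substr(as.character(genomeB[[1]]), 10001, 11000)
  absent <- rndDna(1000)
  cdnas <- Biostrings::DNAStringSet(c(gPresent = present, gAbsent = absent))
  calls <- findCandidates(cdnas, genomeB)
  expect_equal(calls$status[calls$gene == "gPresent"], "placed")
  expect_equal(calls$bestIdentity[calls$gene == "gPresent"], 1)
  expect_equal(calls$status[calls$gene == "gAbsent"], "candidate")
  expect_true(is.na(calls$bestIdentity[calls$gene == "gAbsent"]))
  expect_error(findCandidates(Biostrings::DNAStringSet(), genomeB), "empty")
})

test_that("planted deletions are candidates; shared genes are placed", {
  sim <- simulateGenomePair(smallSimSpec(seed = 509))
  calls <- findCandidates(cdnaSeqs(sim$genomeA), sim$genomeB)
  expect_setequal(calls$gene[calls$status == "candidate"],
                  truthSpecificA(sim$truth))
  om <- truthOrthologs(sim$truth)
  expect_true(all(calls$status[calls$gene %in% om$geneA] == "placed"))
})

test_that("synteny exclusion only reclassifies candidates in the set", {
  calls <- data.frame(gene = c("g1", "g2", "g3"),
                      status = c("candidate", "candidate", "placed"),
                      bestIdentity = NA_real_, bestCoverage = NA_real_,
                      coveredFraction = NA_real_, stringsAsFactors = FALSE)
  expect_identical(excludeSyntenic(calls, character(0)), calls)
  out <- excludeSyntenic(calls, c("g2", "g3"))
  expect_equal(out$status, c("candidate", "syntenic_excluded", "placed"))
})

test_that("coverage confirmation uses a strict < 50% covered-fraction rule", {
  set.seed(59)
  g <- rndDna(3000)
  gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(1001, 2001),
                                                       c(1100, 2100)),
                               strand = "+", gene_id = c("gHalf", "gLess"))
  genome <- GenomeAnnotation(Biostrings::DNAStringSet(c(chr = g)), gr)
  calls <- data.frame(gene = c("gHalf", "gLess"), status = "candidate",
                      bestIdentity = NA_real_, bestCoverage = NA_real_,
                      coveredFraction = NA_real_, stringsAsFactors = FALSE)
  # reads cover exactly 50 of 100 bases of gHalf, 49 of gLess
  reads <- Biostrings::DNAStringSet(setNames(
    substring(g, c(1051, 2052), c(1100, 2101)), c("r1", "r2")))
  out <- coverageConfirm(calls, reads, genome)
  expect_equal(out$coveredFraction, c(0.50, 0.49))
  expect_equal(out$status[out$gene == "gHalf"], "candidate")
  expect_equal(out$status[out$gene == "gLess"], "high_confidence_specific")

  # zero coverage confirms; full coverage never does
  none <- coverageConfirm(calls, Biostrings::DNAStringSet(
    c(rx = substring(g, 1, 50))), genome)
  expect_true(all(none$status == "high_confidence_specific"))
  full <- coverageConfirm(calls, Biostrings::DNAStringSet(setNames(
    substring(g, c(1001, 2001), c(1100, 2100)), c("rA", "rB"))), genome)
  expect_true(all(full$status == "candidate"))
  expect_equal(full$coveredFraction, c(1, 1))
})

test_that("lowering the covered-fraction cut never adds confirmations", {
  sim <- simulateGenomePair(smallSimSpec(seed = 521))
  spec <- smallSimSpec(seed = 521)
  readsB <- simulateReads(sim$genomeB, spec, "readsB")
  pl <- mapReads(readsB, sim$genomeA)
  calls <- findCandidates(cdnaSeqs(sim$genomeA), sim$genomeB)
  hc <- function(f) {
    out <- coverageConfirm(calls, NULL, sim$genomeA,
                           maxCoveredFraction = f, placements = pl)
    out$gene[out$status == "high_confidence_specific"]
  }
  expect_true(all(hc(0.2) %in% hc(0.5)))
  expect_true(all(hc(0.5) %in% hc(0.8)))
})

test_that("the full classification recovers planted sets in both directions", {
  spec <- smallSimSpec(seed = 523, readDepth = 10, readErrorRate = 0)
  sim <- simulateGenomePair(spec)
  hom <- allVsAllHomologs(cdnaSeqs(sim$genomeA), cdnaSeqs(sim$genomeB))
  ss <- syntenicGeneSet(callBlocks(hom, geneOrderIndex(sim$genomeA),
                                   geneOrderIndex(sim$genomeB)))
  readsB <- simulateReads(sim$genomeB, spec, "readsB")
  callsA <- callSpecificGenes(sim$genomeA, sim$genomeB, readsB,
                              syntenicSet = ss$genesA)
  expect_setequal(callsA$gene[callsA$status == "high_confidence_specific"],
                  truthSpecificA(sim$truth))
  # a planted deletion is never syntenic-excluded
  expect_false(any(callsA$status[callsA$gene %in%
                                 truthSpecificA(sim$truth)] ==
                   "syntenic_excluded"))
  # swapping the genotypes recovers the planted B-specific set
  readsA <- simulateReads(sim$genomeA, spec, "readsA")
  callsB <- callSpecificGenes(sim$genomeB, sim$genomeA, readsA,
                              syntenicSet = ss$genesB)
  expect_setequal(callsB$gene[callsB$status == "high_confidence_specific"],
                  truthSpecificB(sim$truth))
})

test_that("partial-gene divergence also yields candidates under the gates", {
  spec <- smallSimSpec(seed = 531, specificMode = "partial")
  sim <- simulateGenomePair(spec)
  # the A-specific locus is replaced, not deleted: B only grows by its
  # own inserted genes
  expect_equal(sum(Biostrings::width(genomeSequences(sim$genomeB))),
               sum(Biostrings::width(genomeSequences(sim$genomeA))) +
                 3L * 999L)
  calls <- findCandidates(cdnaSeqs(sim$genomeA), sim$genomeB)
  expect_setequal(calls$gene[calls$status == "candidate"],
                  truthSpecificA(sim$truth))
})
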