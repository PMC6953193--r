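test_that("self-alignment is perfect and hopeless pairs return nothing", {
  set.seed(42)
  s <- rndDna(400)
  r <- alignLocal(s, s)
  expect_equal(r$identity, 1)
  expect_equal(r$coverage, 1)
  expect_equal(r$strand, "+")
  expect_equal(c(r$qstart, r$qend, r$tstart, r$tend), c(1L, 400L, 1L, 400L))
  expect_null(alignLocal(strrep("A", 120), strrep("C", 250)))
  expect_error(alignLocal("ACGT!", "ACGT"), "alphabet")
  expect_error(alignLocal("", "ACGT"), "empty")
})

test_that("banded extension matches the full Smith-Waterman oracle", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(100:2000, 1)
    q <- rndDna(n)
    q <- mutateSeq(q, rbinom(1, n, 0.05))
    t <- paste0(rndDna(sample(0:300, 1)), q, rndDna(sample(0:300, 1)))
    q2 <- mutateSeq(q, rbinom(1, n, 0.03))
    r <- alignLocal(q2, t)
    expect_false(is.null(r))
    expect_equal(r$score, swOracleScore(q2, t), label = sprintf("case %d", i))
  }
})

test_that("identity of a mismatch-planted query tracks the DP oracle", {
  set.seed(11)
  q <- rndDna(300)
  t <- paste0(rndDna(150), q, rndDna(150))
  qm <- mutateSeq(q, 30)
  r <- alignLocal(qm, t)
  aln <- swOracleAlign(qm, t)
  oid <- Biostrings::nmatch(aln) /
    (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
  expect_lt(abs(r$identity - oid), 0.01)
})

test_that("reverse-strand hits are reported in forward target coordinates", {
  set.seed(3)
  q <- rndDna(300)
  t <- paste0(rndDna(100), q, rndDna(100))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  r <- alignLocal(rc, t)
  expect_equal(r$strand, "-")
  expect_equal(c(r$tstart, r$tend), c(101L, 400L))
  expect_equal(c(r$qstart, r$qend), c(1L, 300L))
  # symmetric scoring: identity is invariant to swapping query and target
  qm <- mutateSeq(q, 12)
  expect_equal(alignLocal(qm, t)$identity, alignLocal(t, qm)$identity)
})

test_that("cDNA placement enforces the identity and coverage gates", {
  set.seed(21)
  genome <- Biostrings::DNAStringSet(c(s1 = rndDna(20000)))
  locus <- substr(as.character(genome[[1]]), 5001, 6000)

  verbatim <- Biostrings::DNAStringSet(c(gx = locus))
  mp <- mapCdna(verbatim, genome)
  expect_equal(nrow(mp$placements), 1L)
  expect_equal(mp$placements$identity, 1)
  expect_equal(mp$placements$tstart, 5001L)
  expect_length(mp$unplaced, 0L)

  # ~21% divergence spread evenly: best placement identity < 0.80
  low <- locus
  for (p in seq(1, 1000, by = 5)) {
    substr(low, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(low, p, p)), 1)
  }
  mpLow <- mapCdna(Biostrings::DNAStringSet(c(glow = low)), genome)
  expect_equal(nrow(mpLow$placements), 0L)
  expect_equal(mpLow$unplaced, "glow")

  # high identity but only 40% of the query present: coverage gate fails
  part <- paste0(substr(locus, 1, 400), rndDna(600))
  mpPart <- mapCdna(Biostrings::DNAStringSet(c(gpart = part)), genome)
  expect_equal(nrow(mpPart$placements), 0L)

  # the identity gate itself: ~10% divergence passes 0.85, fails 0.95
  mid <- mutateSeq(locus, 100)
  midSet <- Biostrings::DNAStringSet(c(gmid = mid))
  expect_gt(nrow(mapCdna(midSet, genome, minIdentity = 0.85)$placements), 0L)
  expect_equal(nrow(mapCdna(midSet, genome, minIdentity = 0.95)$placements), 0L)
})

test_that("raising thresholds never adds placements", {
  set.seed(31)
  genome <- Biostrings::DNAStringSet(c(s1 = rndDna(30000)))
  cd <- lapply(1:6, function(i) {
    o <- sample(25000, 1)
    mutateSeq(substr(as.character(genome[[1]]), o, o + 799), sample(0:150, 1))
  })
  cdnas <- Biostrings::DNAStringSet(setNames(unlist(cd), paste0("c", 1:6)))
  loose <- mapCdna(cdnas, genome, minIdentity = 0.7, minCoverage = 0.3)
  tight <- mapCdna(cdnas, genome, minIdentity = 0.9, minCoverage = 0.6)
  keyOf <- function(p) paste(p$query, p$target, p$tstart, p$tend, p$strand)
  expect_true(all(keyOf(tight$placements) %in% keyOf(loose$placements)))
})

test_that("all-vs-all homologs recover planted orthologs and nothing else", {
  set.seed(51)
  # disjoint random gene sets of >= 300 bp: empty table, and the DP oracle
  # confirms no qualifying alignment exists
  gA <- Biostrings::DNAStringSet(setNames(vapply(1:5, function(i)
    rndDna(400), ""), paste0("a", 1:5)))
  gB <- Biostrings::DNAStringSet(setNames(vapply(1:5, function(i)
    rndDna(400), ""), paste0("b", 1:5)))
  expect_equal(nrow(allVsAllHomologs(gA, gB)), 0L)
  oracleBest <- max(vapply(1:5, function(i)
    swOracleScore(as.character(gA[[i]]), as.character(gB[[i]])), 0))
  expect_lt(oracleBest, 100)

  # identical sets: every gene pairs with itself at identity 1
  self <- allVsAllHomologs(gA, gA)
  expect_true(all(paste0("a", 1:5) %in% self$geneA[self$geneA == self$geneB]))
  expect_true(all(self$identity[self$geneA == self$geneB] == 1))

  # simulated genotype pair with planted synonymous divergence
  sim <- simulateGenomePair(smallSimSpec(orthologKs = 0.05))
  hom <- allVsAllHomologs(cdnaSeqs(sim$genomeA), cdnaSeqs(sim$genomeB))
  om <- truthOrthologs(sim$truth)
  expect_true(all(paste(om$geneA, om$geneB) %in%
                  paste(hom$geneA, hom$geneB)))
})

test_that("contamination fraction counts covered bases without double counting", {
  set.seed(61)
  asm <- Biostrings::DNAStringSet(c(s1 = rndDna(200000)))
  expect_equal(contaminationFraction(asm, Biostrings::DNAStringSet(
    c(x = rndDna(5000))))$matchedBp, 0L)
  cont <- Biostrings::DNAStringSet(
    c(chl = substr(as.character(asm[[1]]), 50001, 55000)))
  r <- contaminationFraction(asm, cont)
  expect_equal(r$matchedBp, 5000L)
  expect_equal(r$fraction, 5000 / 200000)
  # two contaminants sharing the same locus: union, not sum
  cont2 <- c(cont, Biostrings::DNAStringSet(
    c(mit = substr(as.character(asm[[1]]), 52001, 57000))))
  expect_equal(contaminationFraction(asm, cont2)$matchedBp, 7000L)
})
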