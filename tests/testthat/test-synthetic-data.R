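test_that("simulation parameters validate rates, counts and the tree", {
  expect_s4_class(SimulationParams(seed = 1), "SimulationParams")
  expect_error(SimulationParams(snpRate = 1.5), "probabilities")
  expect_error(SimulationParams(nFamilies = 0), "positive")
  expect_error(SimulationParams(ksTargets = c(0.1, -0.2)), ">= 0")
  expect_error(SimulationParams(accessionTree = "not a tree"), "phylo")
})

test_that("zero target Ks yields an identical duplicate", {
  fam <- simulateDuplicatedFamily(
    SimulationParams(seed = 4, ksTargets = 0, cdsCodons = 80), 1)
  expect_identical(fam$ancestor, fam$duplicate)
  expect_identical(fam$realizedMutations, 0L)
})

test_that("duplicates differ only at synonymous positions", {
  p <- SimulationParams(seed = 9, ksTargets = 0.35, cdsCodons = 120)
  for (i in 1:10) {
    fam <- simulateDuplicatedFamily(p, i)
    expect_identical(translateCds(fam$ancestor),
                     translateCds(fam$duplicate))
  }
})

test_that("realized mutation counts are unbiased for targetKs * S", {
  p <- SimulationParams(seed = 21, ksTargets = 0.35, cdsCodons = 300)
  reps <- 500L
  m <- numeric(reps)
  lambda <- numeric(reps)
  for (i in seq_len(reps)) {
    fam <- simulateDuplicatedFamily(p, i)
    m[i] <- fam$realizedMutations
    lambda[i] <- fam$targetKs * fam$synSites
  }
  # total count is Poisson with mean sum(lambda)
  expect_lt(abs(sum(m) - sum(lambda)), 3 * sqrt(sum(lambda)))
})

test_that("family simulation is deterministic given seed and params", {
  p <- SimulationParams(seed = 33, nFamilies = 5, cdsCodons = 60)
  f1 <- simulateFamilies(p)
  f2 <- simulateFamilies(p)
  expect_identical(as.character(f1$sequences), as.character(f2$sequences))
  expect_identical(f1$truth, f2$truth)
})

test_that("planted SSRs are recovered exactly once at matching thresholds", {
  withr::local_seed(5)
  bg <- cleanBackground(600)
  pl <- plantSSRs(bg, data.frame(unit = "AG", repeats = 6, count = 1),
                  seed = 2)
  hits <- scanSSRs(c(u = pl$sequence))
  di <- hits[hits$nt_type == "di", ]
  expect_equal(nrow(di), 1L)
  # flanking background may re-phase the run by at most one base per side
  overlap <- min(di$end, pl$spans$end) - max(di$start, pl$spans$start) + 1L
  expect_gte(overlap, pl$spans$end - pl$spans$start + 1L - 2L)
  expect_gte(di$repeats, 6L)
})

test_that("a four-repeat trinucleotide insert stays below threshold", {
  withr::local_seed(6)
  bg <- cleanBackground(600)
  pl <- plantSSRs(bg, data.frame(unit = "AGC", repeats = 4, count = 1),
                  seed = 3)
  expect_identical(nrow(scanSSRs(c(u = pl$sequence))), 0L)
})

test_that("non-ACGT SSR units are rejected", {
  expect_error(plantSSRs("ACGTACGT", data.frame(unit = "AN", repeats = 6,
                                                count = 1), seed = 1),
               "A, C, G, T")
})

test_that("snpRate 0 yields an empty SNP truth set", {
  sim <- simulateAccessionAlignments(
    SimulationParams(seed = 2, nUnigenes = 3, snpRate = 0))
  expect_identical(nrow(truthSNPs(sim)), 0L)
})

test_that("nFraction 1 makes every read all-N and filter-rejected", {
  sim <- simulateAccessionAlignments(
    SimulationParams(seed = 2, nUnigenes = 2, snpRate = 0, nFraction = 1))
  seqs <- as.character(estReads(sim))
  expect_true(all(grepl("^N+$", seqs)))
  flt <- filterLowQuality(estReads(sim))
  expect_identical(length(flt$kept), 0L)
  expect_identical(length(flt$rejected), length(estReads(sim)))
})

test_that("accession simulation is deterministic and self-consistent", {
  p <- SimulationParams(seed = 14, nUnigenes = 4,
                        ssrSpec = data.frame(unit = "TC", repeats = 7,
                                             count = 2))
  s1 <- simulateAccessionAlignments(p)
  s2 <- simulateAccessionAlignments(p)
  expect_identical(truthSNPs(s1), truthSNPs(s2))
  expect_identical(truthSSRs(s1), truthSSRs(s2))
  expect_identical(as.character(unigeneSeqs(s1)),
                   as.character(unigeneSeqs(s2)))
  # every truth record points at an emitted unigene (validity contract)
  expect_true(all(truthSNPs(s1)$unigene_id %in% names(unigeneSeqs(s1))))
  expect_true(all(estMembership(s1)$est_id %in% names(estReads(s1))))
})

test_that("written simulation round-trips through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulateAccessionAlignments(
    SimulationParams(seed = 8, nUnigenes = 2))
  paths <- writeSimulation(sim, dir)
  memb <- read.delim(paths[["membership"]])
  expect_setequal(memb$est_id, names(estReads(sim)))
  aln <- readAlignedFasta(file.path(dir, "aligned", "UN0001.afa"))
  expect_identical(aln, alignmentMatrices(sim)[["UN0001"]])
})
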