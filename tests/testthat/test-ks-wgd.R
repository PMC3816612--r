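test_that("NG86 site counts always satisfy S + N = 3 x codons", {
  withr::local_seed(19)
  for (t in 1:25) {
    n <- sample(5:60, 1)
    k <- computeKs(randomSenseCodons(n), randomSenseCodons(n),
                   minCodons = 1)
    expect_equal(k$S + k$N, 3 * k$codons)
  }
})

test_that("identical sequences have Ks 0", {
  cds <- randomSenseCodons(40)
  k <- computeKs(cds, cds)
  expect_identical(k$ks, 0)
  expect_identical(k$Sd, 0)
})

test_that("a single synonymous difference gives the hand-computed Ks", {
  # nine 4-fold glycine codons plus GGT/GGC: S = 10, Sd = 1, ps = 0.1
  a <- paste0(strrep("GGG", 9), "GGT")
  b <- paste0(strrep("GGG", 9), "GGC")
  k <- computeKs(a, b, minCodons = 1)
  expect_equal(k$S, 10)
  expect_equal(k$Sd, 1)
  expect_equal(k$ps, 0.1)
  expect_equal(k$ks, -3 / 4 * log(1 - 4 / 3 * 0.1), tolerance = 1e-12)
  expect_equal(k$ks, 0.107325632731, tolerance = 1e-9)
})

test_that("the Jukes-Cantor correction is flagged undefined at ps >= 3/4", {
  # one synonymous difference on a single two-fold codon: ps = 1/S = 3
  k <- computeKs("TTT", "TTC", minCodons = 1)
  expect_equal(k$ps, 3)
  expect_true(is.na(k$ks))
  expect_true(k$undefined[["ks"]])
})

test_that("computeKs matches the path-enumeration oracle", {
  withr::local_seed(23)
  for (t in 1:150) {
    n <- sample(1:10, 1)
    a <- randomSenseCodons(n)
    b <- randomSenseCodons(n)
    got <- computeKs(a, b, minCodons = 1)
    want <- oracleNG86(a, b)
    for (f in c("S", "N", "Sd", "Nd", "ps")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9)
    }
    expect_identical(is.na(got$ks), is.na(want$ks))
    if (!is.na(got$ks)) expect_equal(got$ks, want$ks, tolerance = 1e-9)
  }
})

test_that("the Ks estimator recovers a small target within Monte-Carlo error", {
  p <- SimulationParams(seed = 77, ksTargets = 0.13, cdsCodons = 300)
  reps <- 500L
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    fam <- simulateDuplicatedFamily(p, i)
    est[i] <- computeKs(fam$ancestor, fam$duplicate)$ks
  }
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.13), 3 * se)
})

test_that("at deeper divergence the multiple-hit bias stays bounded", {
  # two-fold degenerate sites saturate below the JC assumption, giving a
  # small systematic offset at Ks 0.35; it must stay well inside the
  # downstream peak tolerance of +/- 0.05
  p <- SimulationParams(seed = 78, ksTargets = 0.35, cdsCodons = 300)
  est <- vapply(1:300, function(i) {
    fam <- simulateDuplicatedFamily(p, i)
    computeKs(fam$ancestor, fam$duplicate)$ks
  }, 0)
  expect_lt(abs(mean(est) - 0.35), 0.03)
})

test_that("longest-ORF translation honours the 100 aa exclusion", {
  # (TAC)n keeps every other frame at n-1 sense codons, so the longest
  # ORF across the six frames is exactly n amino acids
  expect_identical(nchar(translateLongestOrf(strrep("TAC", 100))$protein),
                   100L)
  expect_null(translateLongestOrf(strrep("TAC", 99)))
})

test_that("longest ORF matches an exhaustive six-frame scan", {
  withr::local_seed(29)
  sixFrameBest <- function(s) {
    best <- 0L
    for (x in c(s, revComp(s))) {
      for (f in 1:3) {
        nCod <- (nchar(x) - f + 1L) %/% 3L
        if (nCod < 1L) next
        st <- f + 3L * (seq_len(nCod) - 1L)
        aa <- Biostrings::GENETIC_CODE[substring(x, st, st + 2L)]
        aa[is.na(aa)] <- "*"
        r <- rle(aa == "*")
        runs <- r$lengths[!r$values]
        if (length(runs)) best <- max(best, max(runs))
      }
    }
    best
  }
  for (t in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(80:400, 1),
                      replace = TRUE), collapse = "")
    orf <- translateLongestOrf(s, minAa = 1)
    got <- if (is.null(orf)) 0L else nchar(orf$protein)
    expect_identical(got, sixFrameBest(s))
    if (!is.null(orf)) {
      expect_identical(translateCds(orf$cds), orf$protein)
      expect_false(grepl("\\*", orf$protein))
    }
  }
})

test_that("redundancy removal applies the three rules to the shorter member", {
  lengths <- c(g1 = 900L, g2 = 700L)
  # rule 1: alignment > 600 bp, identity > 95
  st <- data.frame(gene_a = "g1", gene_b = "g2", aln_bp = 700,
                   identity = 96, cov_a = 0.7, cov_b = 0.9)
  expect_identical(removeRedundantCds(lengths, st), "g1")
  # identity below every threshold: both kept
  st$identity <- 90
  expect_setequal(removeRedundantCds(lengths, st), c("g1", "g2"))
  # rule 2: both < 600 bp, alignment > 300 bp
  lens2 <- c(a = 550L, b = 500L)
  st2 <- data.frame(gene_a = "a", gene_b = "b", aln_bp = 350,
                    identity = 96, cov_a = 0.6, cov_b = 0.6)
  expect_identical(removeRedundantCds(lens2, st2), "a")
  # rule 3: >= 95% coverage of one member at >= 95% identity (boundary)
  st3 <- data.frame(gene_a = "a", gene_b = "b", aln_bp = 200,
                    identity = 95, cov_a = 0.5, cov_b = 0.96)
  expect_identical(removeRedundantCds(lens2, st3), "a")
})

test_that("redundancy removal is idempotent and keeps the longer member", {
  withr::local_seed(31)
  ids <- paste0("g", 1:12)
  lengths <- setNames(sample(seq(300L, 1200L, 3L), 12), ids)
  pairs <- t(combn(ids, 2))
  st <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                   aln_bp = sample(100:900, nrow(pairs), TRUE),
                   identity = runif(nrow(pairs), 85, 100),
                   cov_a = runif(nrow(pairs)), cov_b = runif(nrow(pairs)))
  kept <- removeRedundantCds(lengths, st)
  st2 <- st[st$gene_a %in% kept & st$gene_b %in% kept, ]
  expect_identical(removeRedundantCds(lengths[kept], st2), kept)
  # the longest gene overall can never be removed
  expect_true(names(which.max(lengths)) %in% kept)
})

test_that("protein alignment is exact for identity and single deletions", {
  p <- translateCds(randomSenseCodons(80))
  self <- alignProteinPair(p, p)
  expect_equal(self$identity, 100)
  expect_false(grepl("-", self$alignedA))
  del <- paste0(substr(p, 1, 35), substr(p, 46, 80))
  aln <- alignProteinPair(p, del)
  expect_identical(gsub("[^-]", "", aln$alignedB), strrep("-", 10))
  expect_true(grepl("-{10}", aln$alignedB))
})

test_that("alignment scores match the affine dynamic-programming oracle", {
  withr::local_seed(37)
  for (t in 1:25) {
    a <- translateCds(randomSenseCodons(sample(5:50, 1)))
    b <- translateCds(randomSenseCodons(sample(5:50, 1)))
    expect_equal(alignProteinPair(a, b)$score, oracleNWScore(a, b),
                 tolerance = 1e-9)
  }
})

test_that("reciprocal best pairs require mutual top hits", {
  s <- matrix(c(NA, 5, 5, NA), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(reciprocalBestPairs(s)$gene_b, "b")
  # a -> b, b -> c, c -> b: only (b, c)
  s3 <- matrix(c(NA, 1, 0,
                 1, NA, 5,
                 0, 5, NA), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  got <- reciprocalBestPairs(s3)
  expect_identical(nrow(got), 1L)
  expect_identical(c(got$gene_a, got$gene_b), c("b", "c"))
})

test_that("reciprocal best pairs match exhaustive search on random matrices", {
  withr::local_seed(53)
  for (t in 1:30) {
    n <- sample(3:15, 1)
    ids <- paste0("g", seq_len(n))
    s <- matrix(sample(1:20, n * n, TRUE), n, n,
                dimnames = list(ids, ids))
    s <- (s + t(s)) / 2
    norm <- function(df) {
      df <- df[order(df$gene_a, df$gene_b, method = "radix"), ,
               drop = FALSE]
      rownames(df) <- NULL
      df
    }
    got <- norm(reciprocalBestPairs(s)[, c("gene_a", "gene_b")])
    expect_equal(got, norm(oracleRBH(s)), ignore_attr = TRUE)
    # no gene in more than one pair
    expect_false(anyDuplicated(c(got$gene_a, got$gene_b)) > 0)
  }
})

test_that("codon alignment back-translates residue-for-residue", {
  cdsA <- randomSenseCodons(30)
  cdsB <- randomSenseCodons(30)
  pA <- translateCds(cdsA)
  pB <- translateCds(cdsB)
  # gap-free: 3n columns
  cod <- codonAlign(pA, pB, cdsA, cdsB)
  expect_identical(nchar(cod$codonsA), 90L)
  expect_identical(cod$codonsA, cdsA)
  # two gap columns drop the corresponding codons
  gA <- paste0(substr(pA, 1, 10), "--", substr(pA, 11, 30))
  gB <- paste0(substr(pB, 1, 12), substr(pB, 13, 30), "--")
  cod2 <- codonAlign(gA, gB, cdsA, cdsB)
  expect_identical(cod2$nCodons, 28L)   # 32 columns, 4 with a gap
  expect_identical(nchar(cod2$codonsA), 84L)
  expect_error(codonAlign(pA, pB, cdsB, cdsA), "translate")
})

test_that("density peaks localize a unimodal Ks sample", {
  withr::local_seed(59)
  vals <- rnorm(600, 0.35, 0.05)
  kd <- ksDensityPeaks(vals, bandwidth = 0.03)
  expect_true(all(ksValues(kd) > 0 & ksValues(kd) < 3))
  pk <- ksPeaks(kd)
  main <- pk$ks[which.max(pk$height)]
  expect_lt(abs(main - 0.35), 0.03)
  expect_error(ksDensityPeaks(numeric(0)), "no Ks values")
  expect_warning(ksDensityPeaks(runif(10, 0.1, 0.5)), "fewer than 30")
})

test_that("rate calibration inverts the fossil window", {
  r <- calibrateRate(1.5, 54, 90)
  expect_equal(rateInterval(r), c(1.5 / 90, 1.5 / 54), tolerance = 1e-12)
  expect_equal(rateInterval(r), c(0.016667, 0.027778), tolerance = 1e-4)
  expect_error(calibrateRate(0, 54, 90), "> 0")
  expect_error(calibrateRate(1.5, 90, 54), "tMin")
  # doubling the calibration Ks doubles both endpoints
  expect_equal(rateInterval(calibrateRate(3.0, 54, 90)),
               2 * rateInterval(r))
})

test_that("event dating is T = Ks/r, linear and order-correct", {
  rate <- calibrateRate(1.475, 54, 90)
  ev <- dateEvent(0.35, rate)
  expect_lt(ev$t_young, ev$t_old)
  expect_equal(ev$t_young, 0.35 / (1.475 / 54), tolerance = 1e-12)
  ev2 <- dateEvent(0.70, rate)
  expect_equal(c(ev2$t_young, ev2$t_old),
               2 * c(ev$t_young, ev$t_old))
  expect_error(dateEvent(0, rate), "> 0")
})
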