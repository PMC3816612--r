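test_that("dinucleotide threshold is six repeats", {
  hit <- scanSSRs(c(u = "AGAGAGAGAGAG"))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$unit, "AG")
  expect_identical(hit$repeats, 6L)
  expect_identical(c(hit$start, hit$end), c(1L, 12L))
  expect_identical(nrow(scanSSRs(c(u = "AGAGAGAGAG"))), 0L)
})

test_that("runs are broken at N and non-nucleotides are rejected", {
  expect_identical(nrow(scanSSRs(c(u = "AGAGAGNAGAGAGAGAG"))), 0L)
  expect_error(scanSSRs(c(u = "AGAGXAGAG")), "A, C, G, T, N")
})

test_that("non-primitive units are reported at the shortest unit only", {
  # (AG)x12 must not additionally be reported as (AGAG)x6 or (AGAGAG)x4
  hit <- scanSSRs(c(u = strrep("AG", 12)))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$unit, "AG")
  expect_identical(hit$repeats, 12L)
})

test_that("mononucleotide runs are not reported", {
  expect_identical(nrow(scanSSRs(c(u = strrep("A", 30)))), 0L)
})

test_that("scanner matches the brute-force enumeration oracle", {
  withr::local_seed(41)
  for (t in 1:150) {
    s <- paste(sample(c("A", "C", "G", "T", "A", "G", "N"), 400,
                      replace = TRUE), collapse = "")
    if (t %% 3 == 0) {
      s <- plantSSRs(s, data.frame(unit = c("AG", "AAG", "AT"),
                                   repeats = c(7, 6, 6),
                                   count = c(2, 1, 1)), seed = t)$sequence
    }
    got <- scanSSRs(c(x = s))[, c("start", "end", "unit", "repeats")]
    rownames(got) <- NULL
    expect_equal(got, oracleScanSSRs(s), ignore_attr = TRUE)
  }
})

test_that("canonical classes pair a unit with its reverse complement only", {
  expect_identical(canonicalClass("TC"), "GA/TC")
  expect_identical(canonicalClass("GA"), "GA/TC")
  expect_identical(canonicalClass("AG"), "AG/CT")   # distinct from GA/TC
  expect_identical(canonicalClass("AT"), "AT/AT")   # palindromic unit
  expect_error(canonicalClass("ANG"), "ACGT")
  expect_error(canonicalClass("A"), "length 2-6")
})

test_that("adjacent motifs merge into one compound record", {
  s <- paste0(strrep("AG", 6), strrep("TC", 7))
  merged <- mergeCompound(scanSSRs(c(u = s)), maxGap = 100)
  comp <- merged[merged$nt_type == "compound", ]
  expect_identical(nrow(comp), 1L)
  expect_identical(c(comp$start, comp$end), c(1L, 26L))
  expect_identical(sum(merged$in_compound), 2L)
})

test_that("motifs farther apart than maxGap stay separate", {
  withr::local_seed(42)
  spacer <- cleanBackground(150)
  s <- paste0(strrep("AG", 6), spacer, strrep("TC", 7))
  merged <- mergeCompound(scanSSRs(c(u = s)), maxGap = 100)
  expect_identical(sum(merged$nt_type == "compound"), 0L)
  expect_identical(nrow(merged), 2L)
})

test_that("compound spans cover their constituents and never overlap", {
  withr::local_seed(43)
  for (t in 1:20) {
    bg <- cleanBackground(800)
    pl <- plantSSRs(bg, data.frame(unit = c("AG", "TC", "AAG", "CTT"),
                                   repeats = c(6, 7, 5, 6),
                                   count = c(1, 1, 1, 1)), seed = t)
    merged <- mergeCompound(scanSSRs(c(x = pl$sequence)), maxGap = 100)
    comp <- merged[merged$nt_type == "compound", , drop = FALSE]
    const <- merged[merged$in_compound, , drop = FALSE]
    if (nrow(comp) >= 2L) {
      o <- order(comp$start)
      expect_true(all(comp$start[o][-1L] > comp$end[o][-nrow(comp)]))
    }
    for (i in seq_len(nrow(const))) {
      expect_true(any(comp$start <= const$start[i] &
                        comp$end >= const$end[i]))
    }
  }
})

test_that("flank sufficiency counts non-N bases on both sides", {
  s <- c(u = paste0(strrep("C", 50), strrep("AG", 6), strrep("T", 50)))
  m <- scanSSRs(s)
  expect_true(checkFlanks(m, s, minFlank = 50))
  expect_false(checkFlanks(m, s, minFlank = 51))
  # Ns inside the flank do not count
  s2 <- c(u = paste0("N", strrep("C", 49), strrep("AG", 6), strrep("T", 50)))
  expect_false(checkFlanks(scanSSRs(s2), s2, minFlank = 50))
  # motif at the sequence start has no left flank
  s3 <- c(u = paste0(strrep("AG", 6), strrep("T", 80)))
  expect_false(checkFlanks(scanSSRs(s3), s3, minFlank = 1))
})

test_that("flank predicate agrees with a direct recount", {
  withr::local_seed(44)
  for (t in 1:20) {
    bg <- cleanBackground(400)
    pl <- plantSSRs(bg, data.frame(unit = "TA", repeats = 6, count = 1),
                    seed = t)
    s <- c(x = pl$sequence)
    m <- scanSSRs(s)
    m <- m[m$unit %in% c("TA", "AT"), , drop = FALSE]
    expect_identical(nrow(m), 1L)
    chars <- strsplit(pl$sequence, "")[[1]]
    left <- sum(chars[seq_len(m$start - 1L)] != "N")
    right <- sum(chars[seq(m$end + 1L, length(chars))] != "N")
    expect_identical(checkFlanks(m, s, 50), left >= 50 && right >= 50)
  }
})

test_that("summary counts are conserved and compound replaces constituents", {
  s <- c(u1 = paste0(strrep("AG", 6), strrep("TC", 7)),
         u2 = strrep("AAG", 5))
  motifs <- mergeCompound(scanSSRs(s), maxGap = 100)
  sm <- summarizeSSRs(motifs)
  expect_identical(unname(sum(sm$by_type)), unname(sm$n_total))
  expect_identical(unname(sm$by_type[["compound"]]), 1L)
  expect_identical(unname(sm$by_type[["di"]]), 0L) # merged away
  expect_identical(unname(sm$by_type[["tri"]]), 1L)
  expect_identical(sm$n_unigenes_with_ssr, 2L)
})

test_that("empty motif lists summarize to zero", {
  sm <- summarizeSSRs(scanSSRs(c(u = "ACGTACGTAA")))
  expect_identical(unname(sm$n_total), 0L)
  expect_true(all(sm$by_type == 0L))
})
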