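## Homolog pairing, Ks distributions and fossil-calibrated WGD dating.

#' Longest open reading frame across six frames
#'
#' Scans all three frames of both strands and returns the longest run of
#' sense codons (stop-to-stop; no ATG requirement, appropriate for partial
#' cDNA sequences). Ties are broken deterministically: forward frames
#' 1,2,3 then reverse frames 1,2,3, earliest start within a frame.
#'
#' @param sequence Nucleotide string or `DNAString`.
#' @param minAa Minimum protein length; shorter ORFs return `NULL`
#'   (default 100 amino acids, the exclusion threshold of the analysis).
#' @return `NULL`, or a list with `cds`, `protein`, `strand` (`+`/`-`),
#'   `frame` (1-3) and `start` (1-based CDS start on the reported strand).
#' @examples
#' orf <- translateLongestOrf(paste0("CCC", strrep("GGA", 120), "TAACCC"),
#'                            minAa = 100)
#' nchar(orf$protein)
#' @export
translateLongestOrf <- function(sequence, minAa = 100L) {
  sequence <- toupper(as.character(sequence))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revComp(sequence)
    for (frame in 1:3) {
      n <- nchar(s) - frame + 1L
      nCod <- n %/% 3L
      if (nCod < 1L) next
      starts <- frame + 3L * (seq_len(nCod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      aa <- Biostrings::GENETIC_CODE[codons]
      aa[is.na(aa)] <- "X"          # ambiguous codons end an ORF
      isStop <- aa == "*" | aa == "X"
      r <- rle(isStop)
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1L
      for (k in which(!r$values)) {
        len <- r$lengths[k]
        if (!is.null(best) && len <= best$len) next
        cdsStart <- starts[begs[k]]
        best <- list(len = len,
                     cds = substr(s, cdsStart, cdsStart + 3L * len - 1L),
                     strand = strand, frame = frame, start = cdsStart)
      }
    }
  }
  if (is.null(best) || best$len < minAa) return(NULL)
  list(cds = best$cds, protein = translateCds(best$cds),
       strand = best$strand, frame = best$frame, start = best$start)
}

#' Globally align two proteins
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' 10, gap extend 0.5), via `Biostrings::pairwiseAlignment`.
#'
#' @param proteinA,proteinB Amino-acid strings.
#' @param gapOpening,gapExtension Affine gap penalties.
#' @return A list: `alignedA`, `alignedB` (gapped strings of equal
#'   length), `score`, `identity` (percent identity over aligned non-gap
#'   columns), `alignedResidues` (non-gap column count), and `coverage`
#'   of each input (`covA`, `covB`).
#' @export
alignProteinPair <- function(proteinA, proteinB, gapOpening = 10,
                             gapExtension = 0.5) {
  a <- Biostrings::AAString(as.character(proteinA))
  b <- Biostrings::AAString(as.character(proteinB))
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  both <- ca != "-" & cb != "-"
  nres <- sum(both)
  ident <- if (nres) 100 * sum(ca[both] == cb[both]) / nres else 0
  list(alignedA = ga, alignedB = gb, score = Biostrings::score(aln),
       identity = ident, alignedResidues = nres,
       covA = nres / nchar(proteinA), covB = nres / nchar(proteinB))
}

#' Remove redundant coding sequences
#'
#' Applies the three redundancy rules to pairwise alignment statistics,
#' removing the shorter member of a pair when (1) the alignment is longer
#' than 600 bp with more than 95\% amino-acid identity; (2) both CDS are
#' shorter than 600 bp, the alignment longer than 300 bp, with more than
#' 95\% identity; or (3) the aligned region covers at least 95\% of either
#' member with no less than 95\% identity. Pairs are processed sorted by
#' identity then alignment length (descending) with greedy removal, which
#' makes cascades order-independent; the longer member of a pair is never
#' removed (ties remove the lexicographically later id).
#'
#' @param lengths Named integer vector of CDS lengths in bp.
#' @param pairStats `data.frame(gene_a, gene_b, aln_bp, identity, cov_a,
#'   cov_b)` — alignment length in bp (3x aligned residues), percent
#'   amino-acid identity, and aligned coverage of each member in `[0,1]`.
#' @return Character vector of retained gene ids.
#' @export
removeRedundantCds <- function(lengths, pairStats) {
  need <- c("gene_a", "gene_b", "aln_bp", "identity", "cov_a", "cov_b")
  stopifnot(all(need %in% names(pairStats)))
  removed <- character(0)
  if (nrow(pairStats)) {
    ord <- order(-pairStats$identity, -pairStats$aln_bp,
                 pairStats$gene_a, pairStats$gene_b)
    for (i in ord) {
      a <- pairStats$gene_a[i]; b <- pairStats$gene_b[i]
      if (a %in% removed || b %in% removed) next
      la <- lengths[[a]]; lb <- lengths[[b]]
      id <- pairStats$identity[i]; ab <- pairStats$aln_bp[i]
      hit <- (ab > 600 && id > 95) ||
        (la < 600 && lb < 600 && ab > 300 && id > 95) ||
        ((pairStats$cov_a[i] >= 0.95 || pairStats$cov_b[i] >= 0.95) &&
           id >= 95)
      if (hit) {
        shorter <- if (la < lb) a else if (lb < la) b else max(a, b)
        removed <- c(removed, shorter)
      }
    }
  }
  setdiff(names(lengths), removed)
}

#' Reciprocal best pairs from an all-vs-all score matrix
#'
#' `(a, b)` is a pair iff `b` is `a`'s highest-scoring partner and vice
#' versa; score ties are broken by lexicographically smallest partner id.
#' Self scores are ignored; each gene appears in at most one pair.
#'
#' @param scores Square numeric matrix with identical row/column names;
#'   `NA` marks unscored pairs.
#' @return `data.frame(gene_a, gene_b, score)` with `gene_a < gene_b`,
#'   sorted by `gene_a`.
#' @export
reciprocalBestPairs <- function(scores) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            identical(rownames(scores), colnames(scores)))
  ids <- rownames(scores)
  diag(scores) <- NA
  best <- vapply(ids, function(g) {
    s <- scores[g, ]
    if (all(is.na(s))) return(NA_character_)
    m <- max(s, na.rm = TRUE)
    sort(names(s)[!is.na(s) & s == m])[1L]
  }, "")
  rows <- list()
  for (g in ids) {
    h <- best[[g]]
    if (is.na(h) || g >= h) next
    if (identical(best[[h]], g)) {
      rows[[length(rows) + 1L]] <-
        data.frame(gene_a = g, gene_b = h, score = scores[g, h])
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a), , drop = FALSE]
}

#' Back-translate a protein alignment to paired codon columns
#'
#' Maps each aligned residue pair to its codon pair and drops columns where
#' either side is a gap; the output length is divisible by 3.
#'
#' @param alignedA,alignedB Gapped protein strings of equal length.
#' @param cdsA,cdsB The coding sequences; each must translate exactly to
#'   its ungapped protein.
#' @return A list with `codonsA` and `codonsB` (equal-length nucleotide
#'   strings) and `nCodons`.
#' @export
codonAlign <- function(alignedA, alignedB, cdsA, cdsB) {
  ca <- strsplit(toupper(alignedA), "")[[1]]
  cb <- strsplit(toupper(alignedB), "")[[1]]
  stopifnot(length(ca) == length(cb))
  protA <- paste(ca[ca != "-"], collapse = "")
  protB <- paste(cb[cb != "-"], collapse = "")
  if (translateCds(cdsA) != protA || translateCds(cdsB) != protB) {
    stop("CDS does not translate to the aligned protein")
  }
  codA <- splitCodons(cdsA)
  codB <- splitCodons(cdsB)
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  list(codonsA = paste(codA[ia[both]], collapse = ""),
       codonsB = paste(codB[ib[both]], collapse = ""),
       nCodons = sum(both))
}

#' Ks distribution and density peaks
#'
#' Retains Ks values strictly inside (0, 3), fits a Gaussian kernel
#' density on a fixed grid over that range, and reports strict local
#' maxima whose height is at least `minHeightFrac` of the global maximum.
#'
#' @param values Numeric Ks values (`NA` and out-of-range values are
#'   dropped).
#' @param bandwidth Kernel bandwidth in Ks units (default 0.03).
#' @param gridN Grid size (default 600).
#' @param minHeightFrac Peak height floor as a fraction of the maximum
#'   density (default 0.1).
#' @return A [KsDistribution-class] object.
#' @examples
#' d <- ksDensityPeaks(abs(rnorm(500, 0.35, 0.05)) + 1e-4)
#' ksPeaks(d)
#' @export
ksDensityPeaks <- function(values, bandwidth = 0.03, gridN = 600L,
                           minHeightFrac = 0.1) {
  values <- values[!is.na(values) & values > 0 & values < 3]
  if (!length(values)) stop("no Ks values inside (0, 3)")
  if (length(values) < 30L) {
    warning("fewer than 30 Ks values; peaks may be unreliable")
  }
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      from = 0, to = 3, n = gridN)
  y <- d$y
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
               y[2:(n - 1)] > y[3:n], FALSE)
  isMax <- isMax & y >= minHeightFrac * max(y)
  peaks <- data.frame(ks = d$x[isMax], height = y[isMax])
  peaks <- peaks[order(peaks$ks), , drop = FALSE]
  rownames(peaks) <- NULL
  new("KsDistribution", values = values, x = d$x, y = y,
      peaks = peaks, bandwidth = bandwidth)
}

#' Calibrate a substitution-rate interval from a fossil-dated split
#'
#' A split of synonymous divergence `ksCalibration` whose age is bracketed
#' by the fossil window `(tMin, tMax)` million years bounds the rate:
#' `r` in `(ksCalibration/tMax, ksCalibration/tMin)` Ks per million years.
#'
#' @param ksCalibration Ks of the calibration split (> 0).
#' @param tMin,tMax Fossil age window in million years, `0 < tMin < tMax`;
#'   default 54-90 MY (the Capparales fossil interval).
#' @return A [CalibratedRate-class] object.
#' @examples
#' calibrateRate(1.5, 54, 90)
#' @export
calibrateRate <- function(ksCalibration, tMin = 54, tMax = 90) {
  if (ksCalibration <= 0) stop("ksCalibration must be > 0")
  if (!(tMin > 0 && tMax > tMin)) stop("need 0 < tMin < tMax")
  new("CalibratedRate", ksCalibration = ksCalibration,
      tInterval = c(tMin, tMax),
      rInterval = c(ksCalibration / tMax, ksCalibration / tMin))
}

#' Date an event from a Ks peak: T = Ks / r
#'
#' The rate interval maps a Ks peak to an age interval
#' `(ks/r_max, ks/r_min)` in million years; ages scale linearly with the
#' peak location.
#'
#' @param ksPeak Ks location of the event (> 0).
#' @param rate A [CalibratedRate-class] object.
#' @param label Event label (e.g. `"alpha WGD"`).
#' @return `data.frame(label, ks_peak, t_young, t_old)` (MYA).
#' @examples
#' dateEvent(0.35, calibrateRate(1.475, 54, 90), "beta WGD")
#' @export
dateEvent <- function(ksPeak, rate, label = "event") {
  stopifnot(is(rate, "CalibratedRate"))
  if (any(ksPeak <= 0)) stop("ksPeak must be > 0")
  r <- rate@rInterval
  data.frame(label = label, ks_peak = ksPeak,
             t_young = ksPeak / r[2L], t_old = ksPeak / r[1L])
}

## k-mer cosine similarity prefilter used to avoid all-vs-all protein
## alignment at scale; candidates are then aligned exactly.
#' @keywords internal
kmerCandidates <- function(proteins, k = 3L, topN = 3L) {
  ids <- names(proteins)
  counts <- lapply(proteins, function(p) {
    n <- nchar(p)
    if (n < k) return(table(character()))
    table(substring(p, 1:(n - k + 1L), k:n))
  })
  kmers <- unique(unlist(lapply(counts, names)))
  M <- matrix(0, length(ids), length(kmers),
              dimnames = list(ids, kmers))
  for (i in seq_along(ids)) M[i, names(counts[[i]])] <- counts[[i]]
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  sim <- tcrossprod(M / nrm)
  diag(sim) <- -Inf
  lapply(ids, function(g) {
    s <- sim[g, ]
    names(sort(s, decreasing = TRUE))[seq_len(min(topN, length(s) - 1L))]
  }) |> setNames(ids)
}

#' Within-species paralog Ks from a set of coding genes
#'
#' End-to-end convenience wrapper: ranks candidate partners with a k-mer
#' similarity prefilter, aligns candidate protein pairs globally, forms
#' reciprocal best pairs on the alignment scores, back-translates to codon
#' alignments and computes NG86 Ks.
#'
#' @param genes Named list with elements `cds` and `protein` per gene (as
#'   from [translateLongestOrf()]), or a named character vector of CDS.
#' @param topN Candidate partners per gene from the prefilter (default 3).
#' @param minCodons Minimum usable codon pairs for a Ks value.
#' @return `data.frame(gene_a, gene_b, score, ks, ka, S, N)`; `ks` is `NA`
#'   where the Jukes-Cantor correction is undefined.
#' @export
paralogKs <- function(genes, topN = 3L, minCodons = 30L) {
  if (is.character(genes)) {
    genes <- lapply(genes, function(cds)
      list(cds = cds, protein = translateCds(cds)))
  }
  ids <- names(genes)
  prot <- vapply(genes, `[[`, "", "protein")
  cand <- kmerCandidates(prot, topN = topN)
  scores <- matrix(NA_real_, length(ids), length(ids),
                   dimnames = list(ids, ids))
  alnCache <- new.env(parent = emptyenv())
  for (g in ids) {
    for (h in cand[[g]]) {
      if (!is.na(scores[g, h])) next
      key <- paste(sort(c(g, h)), collapse = "|")
      aln <- alnCache[[key]]
      if (is.null(aln)) {
        aln <- alignProteinPair(prot[[g]], prot[[h]])
        alnCache[[key]] <- aln
      }
      scores[g, h] <- scores[h, g] <- aln$score
    }
  }
  pairs <- reciprocalBestPairs(scores)
  if (!nrow(pairs)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), ks = numeric(), ka = numeric(),
                      S = numeric(), N = numeric()))
  }
  extra <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_a[i]; h <- pairs$gene_b[i]
    aln <- alnCache[[paste(sort(c(g, h)), collapse = "|")]]
    cod <- codonAlign(aln$alignedA, aln$alignedB,
                      genes[[g]]$cds, genes[[h]]$cds)
    k <- computeKs(cod$codonsA, cod$codonsB, minCodons = minCodons)
    data.frame(ks = k$ks, ka = k$ka, S = k$S, N = k$N)
  })
  cbind(pairs, do.call(rbind, extra))
}
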