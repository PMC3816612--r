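## SNP calling from per-unigene multi-accession EST alignments:
## >= 2x coverage per accession, internal monomorphism, and no shared base
## between the compared accessions; transition/transversion/indel classes.

#' Classify a SNP allele pair
#'
#' `A/G` and `C/T` are transitions; any other base/base pair is a
#' transversion; any pair involving the gap symbol `-` is a single-base
#' indel.
#'
#' @param a,b Distinct symbols from `A,C,G,T,-`.
#' @return One of `"transition"`, `"transversion"`, `"indel"`.
#' @examples
#' classifySNP("A", "G")
#' classifySNP("T", "-")
#' @export
classifySNP <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- c("A", "C", "G", "T", "-")
  if (!a %in% ok || !b %in% ok) stop("alleles must be A, C, G, T or -")
  if (a == b) stop("allele pair members must be distinct")
  if (a == "-" || b == "-") return("indel")
  pair <- paste(sort(c(a, b)), collapse = "")
  if (pair %in% c("AG", "CT")) "transition" else "transversion"
}

## Resolve per-accession alleles for every column of one alignment:
## an accession gets an allele where it has >= minCoverage non-N
## observations, all identical (internal monomorphism); otherwise NA.
#' @keywords internal
resolveAccessionAlleles <- function(aln, accOf, accessions, minCoverage) {
  symbols <- c("A", "C", "G", "T", "-")
  L <- ncol(aln)
  res <- matrix(NA_character_, length(accessions), L,
                dimnames = list(accessions, NULL))
  for (a in accessions) {
    rows <- aln[accOf == a, , drop = FALSE]
    counts <- vapply(symbols, function(s) colSums(rows == s), numeric(L))
    counts <- matrix(counts, nrow = L, ncol = length(symbols))
    cov <- rowSums(counts)
    top <- max.col(counts, ties.method = "first")
    ok <- cov >= minCoverage & counts[cbind(seq_len(L), top)] == cov
    res[a, ok] <- symbols[top[ok]]
  }
  res
}

#' Call SNPs from per-unigene alignment matrices
#'
#' A column yields a SNP when two accessions each have at least
#' `minCoverage` non-N observations, each is internally monomorphic, and
#' their observed bases are disjoint (with monomorphic accessions this
#' means different alleles); a gap against a base is a single-base indel.
#' Each (column, allele pair) is reported once, however many accession
#' pairs support it. Calls are symmetric in accession order. Indel calls
#' belonging to a gap run longer than one column are discarded (only
#' single-base indels are scored). Columns with no usable observation are
#' skipped; one warning summarizes how many.
#'
#' @param alignments Named list of character matrices (reads x columns;
#'   symbols `A,C,G,T,N,-` plus `.` for no coverage), as produced by
#'   [simulateAccessionAlignments()] or [readAlignedFasta()].
#' @param accessionOf Named character vector mapping read id to accession,
#'   or a membership `data.frame(est_id, ..., accession)`.
#' @param minCoverage Minimum reads per accession at the site (default 2).
#' @return `data.frame(unigene_id, column, allele_a, allele_b, snp_class)`
#'   followed by one allele column per accession (`NA` when that accession
#'   is unresolved at the site).
#' @export
callSNPs <- function(alignments, accessionOf, minCoverage = 2L) {
  if (is.data.frame(accessionOf)) {
    accessionOf <- setNames(accessionOf$accession, accessionOf$est_id)
  }
  accessions <- sort(unique(unname(accessionOf)))
  out <- list()
  nSkipped <- 0L
  for (uid in names(alignments)) {
    aln <- alignments[[uid]]
    accOf <- accessionOf[rownames(aln)]
    if (anyNA(accOf)) stop("reads in ", uid, " missing from accession map")
    usable <- colSums(matrix(!(aln %in% c("N", ".")), nrow(aln)))
    nSkipped <- nSkipped + sum(usable == 0L)
    resolved <- resolveAccessionAlleles(aln, accOf, accessions,
                                        minCoverage)
    nDistinct <- apply(resolved, 2L, function(cc)
      length(unique(cc[!is.na(cc)])))
    for (j in which(nDistinct >= 2L)) {
      al <- setNames(resolved[, j], accessions)
      ## two most frequent alleles across accessions; ties lexicographic
      tab <- table(al)
      cand <- names(tab)[order(-as.integer(tab), names(tab))]
      pair <- sort(cand[seq_len(2L)])
      ## single-base indels only: drop calls inside longer gap runs
      if ("-" %in% pair) {
        gapAcc <- names(al)[!is.na(al) & al == "-"]
        adjacent <- intersect(c(j - 1L, j + 1L), seq_len(ncol(aln)))
        multi <- any(vapply(adjacent, function(jj) {
          any(resolved[gapAcc, jj] == "-", na.rm = TRUE)
        }, NA))
        if (multi) next
      }
      row <- data.frame(unigene_id = uid, column = j,
                        allele_a = pair[1L], allele_b = pair[2L],
                        snp_class = classifySNP(pair[1L], pair[2L]))
      for (a in accessions) row[[a]] <- al[[a]]
      out[[length(out) + 1L]] <- row
    }
  }
  if (nSkipped > 0L) {
    warning(nSkipped, " alignment columns had no usable observation")
  }
  if (!length(out)) {
    res <- data.frame(unigene_id = character(), column = integer(),
                      allele_a = character(), allele_b = character(),
                      snp_class = character())
    for (a in accessions) res[[a]] <- character()
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$unigene_id, res$column), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build an accession-by-site genotype matrix from SNP calls
#'
#' Sites are ordered by (unigene, column). With `requireComplete = TRUE`
#' (the input the accession phylogeny uses), only sites with a resolved
#' allele in every listed accession are retained.
#'
#' @param snps Output of [callSNPs()].
#' @param accessions Accession names (default: the allele columns present).
#' @param requireComplete Keep only fully informative sites (default TRUE).
#' @return A [GenotypeMatrix-class]; zero columns when no site survives.
#' @export
buildGenotypeMatrix <- function(snps, accessions = NULL,
                                requireComplete = TRUE) {
  fixed <- c("unigene_id", "column", "allele_a", "allele_b", "snp_class")
  if (is.null(accessions)) accessions <- setdiff(names(snps), fixed)
  stopifnot(length(accessions) > 0L)
  snps <- snps[order(snps$unigene_id, snps$column), , drop = FALSE]
  m <- t(as.matrix(snps[, accessions, drop = FALSE]))
  rownames(m) <- accessions
  colnames(m) <- paste(snps$unigene_id, snps$column, sep = ":")
  keep <- rep(TRUE, ncol(m))
  if (requireComplete && ncol(m)) keep <- colSums(is.na(m)) == 0L
  new("GenotypeMatrix",
      alleles = m[, keep, drop = FALSE],
      sites = data.frame(unigene_id = snps$unigene_id,
                         column = snps$column,
                         allele_pair = paste(snps$allele_a, snps$allele_b,
                                             sep = "/"),
                         snp_class = snps$snp_class)[keep, , drop = FALSE])
}
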