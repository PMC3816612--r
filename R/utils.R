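#' @keywords internal
.BASES <- c("A", "C", "G", "T")

## Run code under a fixed RNG seed, restoring the caller's RNG state after.
#' @keywords internal
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Stable small-integer seed derived from a master seed and a stream index.
#' @keywords internal
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483587)
}

#' Reverse complement of a plain nucleotide string
#' @keywords internal
revComp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

#' @keywords internal
asCharacterSeqs <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq1"
  } else {
    out <- setNames(as.character(x), names(x))
  }
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out[] <- toupper(out)
  out
}

#' Translate a coding sequence with the standard genetic code
#'
#' Stop codons translate to `*`; codons containing characters other than
#' A/C/G/T translate to `X`.
#'
#' @param cds A nucleotide string whose length is a multiple of 3.
#' @return The amino-acid string.
#' @examples
#' translateCds("ATGGGGTAA")
#' @export
translateCds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3")
  }
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @keywords internal
splitCodons <- function(cds) {
  cds <- toupper(as.character(cds))
  stopifnot(nchar(cds) %% 3L == 0L)
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Sample a random stop-free coding sequence
#'
#' Codons are drawn uniformly from the 61 sense codons of the standard code;
#' the result carries no internal stop codon in frame 1.
#'
#' @param nCodons Number of codons.
#' @return A nucleotide string of length `3 * nCodons`.
#' @export
randomCds <- function(nCodons) {
  stopifnot(nCodons >= 1)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

## ---- tabular / sequence IO helpers -------------------------------------

#' Read a tab-delimited table
#' @keywords internal
readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' @keywords internal
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write per-unigene alignment matrices as aligned FASTA
#'
#' Rows are reads; `-` marks an alignment gap (a deletion allele) while `.`
#' marks positions outside the read (no coverage). One file per unigene.
#'
#' @param aln A character matrix (reads x columns) with rownames.
#' @param path File path.
#' @return `readAlignedFasta` returns the character matrix.
#' @export
writeAlignedFasta <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeAlignedFasta
#' @export
readAlignedFasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  wid <- unique(nchar(seqs))
  if (length(wid) != 1L) stop("aligned FASTA rows have unequal widths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- ids
  m
}
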