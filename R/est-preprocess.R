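## EST quality filtering and unigene assembly summary statistics.

#' Filter low-quality ESTs by N fraction
#'
#' An EST is rejected when its fraction of N bases exceeds `maxNFraction`
#' (strictly greater; a 100 bp read with exactly 3 Ns passes the default
#' 3\% threshold). N counting is case-insensitive; other IUPAC ambiguity
#' codes are not counted as N. The kept/rejected partition is exhaustive
#' and disjoint.
#'
#' @param ests A `DNAStringSet` (or named character vector) of EST reads.
#' @param maxNFraction Maximum tolerated N fraction, in `[0, 1]`;
#'   default 0.03.
#' @return A list with `kept` and `rejected` `DNAStringSet`s.
#' @examples
#' ests <- Biostrings::DNAStringSet(c(a = "ACGTACGTNN", b = "ACGTACGTAC"))
#' filterLowQuality(ests, maxNFraction = 0.1)
#' @export
filterLowQuality <- function(ests, maxNFraction = 0.03) {
  stopifnot(maxNFraction >= 0, maxNFraction <= 1)
  if (!is(ests, "XStringSet")) {
    ests <- Biostrings::DNAStringSet(toupper(as.character(ests)))
  }
  if (!length(ests)) {
    return(list(kept = ests, rejected = ests))
  }
  nFrac <- as.vector(Biostrings::letterFrequency(ests, "N")) /
    Biostrings::width(ests)
  rejected <- nFrac > maxNFraction
  list(kept = ests[!rejected], rejected = ests[rejected])
}

#' Membership bins of the unigene size distribution
#'
#' The default binning of the radish unigene table: exact counts 1-10, then
#' 11-30, 31-50, 51-70, 71-90, 91-110 and >110 members.
#'
#' @return `data.frame(label, lo, hi)` with `hi = Inf` for the open bin.
#' @export
defaultMembershipBins <- function() {
  data.frame(
    label = c(as.character(1:10), "11-30", "31-50", "51-70", "71-90",
              "91-110", ">110"),
    lo = c(1:10, 11, 31, 51, 71, 91, 111),
    hi = c(1:10, 30, 50, 70, 90, 110, Inf)
  )
}

#' Distribution of EST members per unigene
#'
#' Counts unigenes and their member ESTs per size bin. For exact bins the
#' EST column is `bin * n_unigenes` by construction; the grand total of
#' `n_ests` equals the number of assembled ESTs.
#'
#' @param memberCounts Integer vector of member counts (one per unigene),
#'   or a membership `data.frame` with a `unigene_id` column.
#' @param bins Bin table as from [defaultMembershipBins()]; bins must not
#'   overlap and must cover all observed counts.
#' @return `data.frame(label, lo, hi, n_unigenes, n_ests)`.
#' @examples
#' membershipDistribution(c(1, 2, 2, 5))
#' @export
membershipDistribution <- function(memberCounts,
                                   bins = defaultMembershipBins()) {
  if (is.data.frame(memberCounts)) {
    memberCounts <- as.vector(table(memberCounts$unigene_id))
  }
  memberCounts <- as.integer(memberCounts)
  stopifnot(all(memberCounts >= 1L))
  o <- order(bins$lo)
  bins <- bins[o, , drop = FALSE]
  if (any(bins$lo[-1L] <= bins$hi[-nrow(bins)])) {
    stop("membership bins overlap")
  }
  idx <- findInterval(memberCounts, bins$lo)
  if (any(idx == 0L) || any(memberCounts > bins$hi[idx])) {
    stop("membership bins do not cover all observed counts")
  }
  nU <- tabulate(idx, nbins = nrow(bins))
  nE <- vapply(seq_len(nrow(bins)), function(b)
    sum(memberCounts[idx == b]), 0)
  data.frame(label = bins$label, lo = bins$lo, hi = bins$hi,
             n_unigenes = nU, n_ests = as.integer(nE))
}

#' Totals and large-unigene share of a membership distribution
#'
#' Reporter over a (possibly externally supplied) membership distribution:
#' recomputes `n_ests = lo * n_unigenes` for exact bins (the Table-style
#' identity), totals ESTs and unigenes, and summarizes the unigenes with at
#' least `minMembers` members and the percentage of EST reads they absorb.
#'
#' @param dist `data.frame` with columns `lo`, `hi`, `n_unigenes` and, for
#'   range bins, `n_ests`.
#' @param minMembers Threshold for the "large unigene" summary; default 10.
#' @return A list: `total_ests`, `total_unigenes`, `n_unigenes_large`,
#'   `n_ests_large`, `est_share_large_pct`.
#' @export
membershipSummary <- function(dist, minMembers = 10L) {
  stopifnot(all(c("lo", "hi", "n_unigenes") %in% names(dist)))
  exact <- dist$lo == dist$hi
  nE <- numeric(nrow(dist))
  nE[exact] <- dist$lo[exact] * dist$n_unigenes[exact]
  if (any(!exact)) {
    if (!"n_ests" %in% names(dist)) {
      stop("range bins require an n_ests column")
    }
    nE[!exact] <- dist$n_ests[!exact]
  }
  large <- dist$lo >= minMembers
  total <- sum(nE)
  list(total_ests = total,
       total_unigenes = sum(dist$n_unigenes),
       n_unigenes_large = sum(dist$n_unigenes[large]),
       n_ests_large = sum(nE[large]),
       est_share_large_pct = 100 * sum(nE[large]) / total)
}

#' Unigene summary statistics
#'
#' Counts and mean consensus lengths of all unigenes, contigs (>= 2
#' members) and singletons. Lengths are consensus lengths, not member-read
#' lengths.
#'
#' @param consensus `DNAStringSet` (or named character) of unigene
#'   consensus sequences.
#' @param membership `data.frame(est_id, unigene_id, ...)`; every
#'   `unigene_id` must appear in `consensus`.
#' @return A list: `n_unigenes`, `n_contigs`, `n_singletons`, `mean_length`,
#'   `mean_length_contig`, `mean_length_singleton`.
#' @export
unigeneStats <- function(consensus, membership) {
  seqs <- asCharacterSeqs(consensus)
  counts <- table(membership$unigene_id)
  if (!all(names(counts) %in% names(seqs))) {
    stop("membership refers to unigenes missing from the consensus set")
  }
  len <- nchar(seqs[names(counts)])
  single <- counts == 1L
  list(n_unigenes = length(counts),
       n_contigs = sum(!single),
       n_singletons = sum(single),
       mean_length = mean(len),
       mean_length_contig = if (any(!single)) mean(len[!single]) else NA_real_,
       mean_length_singleton = if (any(single)) mean(len[single]) else NA_real_)
}
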