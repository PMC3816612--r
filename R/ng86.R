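## Nei-Gojobori (1986) synonymous/nonsynonymous counting with Jukes-Cantor
## multiple-hit correction. Per-codon site counts and per-codon-pair
## difference counts are tabulated once per session and reused, so Ks for a
## pair of aligned CDS reduces to table lookups.

.ng86Cache <- new.env(parent = emptyenv())

#' @keywords internal
allCodons <- function() {
  g <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

## All permutations of an integer vector (k <= 3 in practice).
#' @keywords internal
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' NG86 lookup tables
#'
#' Builds (once) the per-codon synonymous site counts and the per-codon-pair
#' synonymous/nonsynonymous difference counts of the Nei-Gojobori method.
#' Site counts: at each codon position the synonymous fraction of the three
#' possible single-base changes contributes 1/3 of a site; changes creating
#' a stop codon count as nonsynonymous, so S + N = 3 per codon. Difference
#' counts between two codons average the synonymous/nonsynonymous step
#' classification over all minimal mutation paths, excluding paths that pass
#' through a stop codon (all paths are used if every path hits a stop).
#'
#' @return A list with `codons`, `synSites` (named numeric, NA for stops),
#'   and 64x64 matrices `sd` and `nd`.
#' @keywords internal
ng86Tables <- function() {
  if (!is.null(.ng86Cache$tab)) return(.ng86Cache$tab)
  gc_ <- Biostrings::GENETIC_CODE
  codons <- allCodons()
  aa <- gc_[codons]
  nC <- length(codons)

  ## per-codon synonymous site counts
  synSites <- setNames(rep(NA_real_, nC), codons)
  for (c1 in codons) {
    if (aa[c1] == "*") next
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, substr(c1, pos, pos))) {
        c2 <- c1
        substr(c2, pos, pos) <- b
        if (gc_[c2] == aa[c1]) s <- s + 1 / 3
      }
    }
    synSites[c1] <- s
  }

  ## per-pair difference counts over all minimal mutation paths
  sdM <- matrix(0, nC, nC, dimnames = list(codons, codons))
  ndM <- sdM
  chars <- do.call(rbind, strsplit(codons, ""))
  rownames(chars) <- codons
  for (i in seq_len(nC)) {
    for (j in seq_len(nC)) {
      if (i == j) next
      c1 <- codons[i]; c2 <- codons[j]
      diffPos <- which(chars[i, ] != chars[j, ])
      paths <- .perms(diffPos)
      stepCounts <- lapply(paths, function(ord) {
        cur <- c1
        syn <- 0; nsyn <- 0; hitStop <- FALSE
        for (k in seq_along(ord)) {
          nxt <- cur
          substr(nxt, ord[k], ord[k]) <- chars[j, ord[k]]
          if (gc_[nxt] == gc_[cur]) syn <- syn + 1 else nsyn <- nsyn + 1
          if (k < length(ord) && gc_[nxt] == "*") hitStop <- TRUE
          cur <- nxt
        }
        c(syn = syn, nsyn = nsyn, stop = as.numeric(hitStop))
      })
      m <- do.call(rbind, stepCounts)
      keep <- m[, "stop"] == 0
      if (!any(keep)) keep <- rep(TRUE, nrow(m))
      sdM[i, j] <- mean(m[keep, "syn"])
      ndM[i, j] <- mean(m[keep, "nsyn"])
    }
  }
  .ng86Cache$tab <- list(codons = codons, synSites = synSites,
                         sd = sdM, nd = ndM)
  .ng86Cache$tab
}

#' Synonymous site count of a coding sequence
#'
#' NG86 synonymous site count: each codon contributes the fraction of its
#' nine possible single-base changes that are synonymous, times 3.
#'
#' @param cds Nucleotide string, length a multiple of 3, no internal stop.
#' @return Total synonymous sites (numeric).
#' @examples
#' synonymousSites("GGGGGG") # two four-fold degenerate codons -> 2
#' @export
synonymousSites <- function(cds) {
  tab <- ng86Tables()
  codons <- splitCodons(cds)
  s <- tab$synSites[codons]
  if (anyNA(s)) stop("CDS contains a stop codon or non-ACGT characters")
  sum(s)
}

#' Synonymous substitution distance (Ks) between two aligned CDS
#'
#' Implements the Nei-Gojobori (1986) method: synonymous (S) and
#' nonsynonymous (N) site counts are averaged over the two sequences;
#' synonymous and nonsynonymous differences are counted per codon pair,
#' averaging over all minimal mutation paths; the proportions are corrected
#' for multiple hits with the Jukes-Cantor formula
#' `K = -3/4 log(1 - 4/3 p)`. The correction is undefined when `p >= 3/4`;
#' such estimates are returned as `NA` and flagged.
#'
#' Codon pairs where either codon contains a non-ACGT character or is a stop
#' codon are excluded from all counts.
#'
#' @param cdsA,cdsB Aligned nucleotide strings of equal length divisible
#'   by 3 (gap columns already removed, e.g. by [codonAlign()]).
#' @param minCodons Minimum usable codon pairs required (default 30, the
#'   shortest alignment worth a distance; lower it for toy examples).
#' @return A list: `ks`, `ka`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `codons`
#'   (usable codon pairs), and logical `undefined` flags for ks/ka.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @examples
#' computeKs("GGGGGT", "GGGGGC", minCodons = 1)$ks
#' @export
computeKs <- function(cdsA, cdsB, minCodons = 30L) {
  cdsA <- toupper(as.character(cdsA))
  cdsB <- toupper(as.character(cdsB))
  if (nchar(cdsA) != nchar(cdsB)) stop("aligned CDS must have equal length")
  tab <- ng86Tables()
  ca <- splitCodons(cdsA)
  cb <- splitCodons(cdsB)
  ok <- ca %in% tab$codons & cb %in% tab$codons
  ok[ok] <- !is.na(tab$synSites[ca[ok]]) & !is.na(tab$synSites[cb[ok]])
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  if (n < minCodons) {
    stop("fewer than ", minCodons, " usable codon pairs (", n, ")")
  }
  S <- (sum(tab$synSites[ca]) + sum(tab$synSites[cb])) / 2
  N <- 3 * n - S
  idx <- cbind(match(ca, tab$codons), match(cb, tab$codons))
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  ks <- jc(ps); ka <- jc(pn)
  list(ks = ks, ka = ka, S = S, N = N, Sd = Sd, Nd = Nd,
       ps = ps, pn = pn, codons = n,
       undefined = c(ks = is.na(ks), ka = is.na(ka)))
}
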