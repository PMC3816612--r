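## Perfect microsatellite (SSR) detection with MISA-style thresholds,
## compound-motif merging and Table-style summaries.

.NT_TYPES <- c(`2` = "di", `3` = "tri", `4` = "tetra", `5` = "penta",
               `6` = "hexa")

#' Default minimum repeat counts per unit length
#'
#' Six repeats for di-nucleotide units, five for tri- through
#' hexa-nucleotide units.
#'
#' @return Named integer vector over unit lengths "2".."6".
#' @export
defaultSSRThresholds <- function() {
  c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

## TRUE when the unit is a repetition of a shorter unit (e.g. "ATAT").
#' @keywords internal
isPrimitiveUnit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(unit, 1L, d), u %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical strand class of an SSR unit
#'
#' Pairs a unit with its reverse complement only (no rotation collapsing:
#' TC/GA and AG/CT are distinct classes). The label puts the
#' lexicographically smaller member first, so `"TC"` and `"GA"` both map to
#' `"GA/TC"`.
#'
#' @param unit ACGT string of length 2-6 (vectorized).
#' @return Character vector of class labels `"X/Y"`.
#' @examples
#' canonicalClass(c("TC", "AG", "AT"))
#' @export
canonicalClass <- function(unit) {
  unit <- toupper(unit)
  if (any(nchar(unit) < 2L | nchar(unit) > 6L) ||
      any(grepl("[^ACGT]", unit))) {
    stop("SSR units must be ACGT strings of length 2-6")
  }
  rc <- vapply(unit, revComp, "")
  paste(pmin(unit, rc), pmax(unit, rc), sep = "/")
}

#' Scan sequences for perfect SSR motifs
#'
#' Reports every maximal perfect tandem run whose repeat count meets the
#' threshold for its unit length. Runs containing N are broken at the N; a
#' reported run cannot be extended by one more full unit on either side;
#' units that are repetitions of a shorter unit are not reported, and no
#' reported motif is a sub-interval of another reported motif with a
#' shorter-or-equal unit (the shortest-unit description wins). A periodic
#' region whose length is not an exact multiple of the unit admits several
#' phase-shifted descriptions of the same run; the run is reported once, at
#' its leftmost phase.
#'
#' @param seqs `DNAStringSet` or named character vector (uppercase ACGTN).
#' @param thresholds Named minimum repeat counts as from
#'   [defaultSSRThresholds()].
#' @return `data.frame(seq_id, start, end, unit, repeats, nt_type, class)`
#'   with 1-based inclusive coordinates, sorted by sequence and start.
#' @examples
#' scanSSRs(c(u1 = "AAAGAGAGAGAGAGTTT"))
#' @export
scanSSRs <- function(seqs, thresholds = defaultSSRThresholds()) {
  seqs <- asCharacterSeqs(seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequences must contain only A, C, G, T, N")
  }
  out <- list()
  for (sid in names(seqs)) {
    s <- strsplit(seqs[[sid]], "")[[1]]
    L <- length(s)
    ok <- s != "N"
    rows <- list()
    for (u in 2:6) {
      minRep <- thresholds[[as.character(u)]]
      if (L < u * minRep) next
      i1 <- seq_len(L - u)
      m <- s[i1] == s[i1 + u] & ok[i1] & ok[i1 + u]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        span <- r$lengths[k] + u        # length of the periodic region
        reps <- span %/% u
        if (reps < minRep) next
        st <- starts[k]
        unit <- paste(s[st:(st + u - 1L)], collapse = "")
        if (!isPrimitiveUnit(unit)) next
        rows[[length(rows) + 1L]] <-
          data.frame(seq_id = sid, start = st, end = st + reps * u - 1L,
                     unit = unit, repeats = reps)
      }
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    ## shortest-unit description wins on contained intervals
    ul <- nchar(df$unit)
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(df))) {
        if (i == j) next
        if (df$start[j] <= df$start[i] && df$end[j] >= df$end[i] &&
            ul[j] <= ul[i] &&
            !(df$start[j] == df$start[i] && df$end[j] == df$end[i] &&
              ul[j] == ul[i] && j > i)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    out[[length(out) + 1L]] <- df[keep, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), unit = character(),
                      repeats = integer(), nt_type = character(),
                      class = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start, nchar(res$unit)), , drop = FALSE]
  res$nt_type <- .NT_TYPES[as.character(nchar(res$unit))]
  res$class <- canonicalClass(res$unit)
  rownames(res) <- NULL
  res
}

#' Merge nearby motifs into compound SSRs
#'
#' Consecutive motifs on the same sequence whose gap is at most `maxGap`
#' base pairs merge (transitively) into one compound record spanning the
#' constituents; constituents are flagged via `in_compound` and compound
#' rows carry `nt_type = "compound"` and a `+`-joined unit label. Use
#' `maxGap = Inf` for the literal "separated by any number of base pairs"
#' behaviour.
#'
#' @param motifs Output of [scanSSRs()].
#' @param maxGap Maximum inter-motif gap in bp (default 100).
#' @return The motif table with an `in_compound` flag and appended
#'   compound rows.
#' @export
mergeCompound <- function(motifs, maxGap = 100) {
  stopifnot(maxGap >= 0)
  motifs$in_compound <- logical(nrow(motifs))
  if (!nrow(motifs)) return(motifs)
  motifs <- motifs[order(motifs$seq_id, motifs$start), , drop = FALSE]
  rownames(motifs) <- NULL
  compound <- list()
  for (sid in unique(motifs$seq_id)) {
    idx <- which(motifs$seq_id == sid)
    if (length(idx) < 2L) next
    gap <- motifs$start[idx[-1L]] - motifs$end[idx[-length(idx)]] - 1L
    grp <- cumsum(c(0L, gap > maxGap))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) < 2L) next
      motifs$in_compound[members] <- TRUE
      compound[[length(compound) + 1L]] <- data.frame(
        seq_id = sid,
        start = min(motifs$start[members]),
        end = max(motifs$end[members]),
        unit = paste(motifs$unit[members], collapse = "+"),
        repeats = NA_integer_, nt_type = "compound",
        class = NA_character_, in_compound = FALSE)
    }
  }
  if (length(compound)) {
    motifs <- rbind(motifs, do.call(rbind, compound))
    motifs <- motifs[order(motifs$seq_id, motifs$start), , drop = FALSE]
    rownames(motifs) <- NULL
  }
  motifs
}

#' Flanking-sequence sufficiency of a motif
#'
#' `TRUE` when at least `minFlank` non-N bases lie on each side of the
#' motif span — the prerequisite for primer design.
#'
#' @param motifs Motif table (needs `seq_id`, `start`, `end`).
#' @param seqs The scanned sequences.
#' @param minFlank Minimum flank length (default 50).
#' @return Logical vector, one entry per motif row.
#' @export
checkFlanks <- function(motifs, seqs, minFlank = 50L) {
  stopifnot(minFlank >= 0)
  seqs <- asCharacterSeqs(seqs)
  vapply(seq_len(nrow(motifs)), function(i) {
    s <- seqs[[motifs$seq_id[i]]]
    if (is.na(s)) stop("motif refers to an unknown sequence")
    if (motifs$start[i] < 1L || motifs$end[i] > nchar(s)) {
      stop("motif span outside its sequence")
    }
    left <- substr(s, 1L, motifs$start[i] - 1L)
    right <- substr(s, motifs$end[i] + 1L, nchar(s))
    nonN <- function(x) nchar(gsub("N", "", x))
    nonN(left) >= minFlank && nonN(right) >= minFlank
  }, NA)
}

#' Marginal totals and shares for SSR count tables
#'
#' Shared reporter behind [summarizeSSRs()] and the worked example on the
#' published radish counts: totals each margin and expresses shares as
#' percentages of the grand total (rounded to integers for reporting).
#'
#' @param byType Named counts per nucleotide type (including `compound`).
#' @param byRepeat Named counts per repeat number (optional).
#' @param byClass Named counts per canonical class (optional).
#' @return A list: `n_total`, `by_type`, `by_repeat`, `by_class`,
#'   `pct_type`, `pct_repeat`, `pct_class`.
#' @export
summarizeSSRCounts <- function(byType, byRepeat = NULL, byClass = NULL) {
  nTotal <- sum(byType)
  pct <- function(x) if (is.null(x)) NULL else
    round(100 * x / nTotal)
  list(n_total = nTotal,
       by_type = byType, by_repeat = byRepeat, by_class = byClass,
       pct_type = pct(byType), pct_repeat = pct(byRepeat),
       pct_class = pct(byClass))
}

#' Summarize detected SSR motifs
#'
#' Counts by nucleotide type, repeat number and canonical class. Compound
#' records replace their constituents in all totals (a motif flagged
#' `in_compound` is only counted through its compound record).
#'
#' @param motifs Output of [scanSSRs()], optionally after
#'   [mergeCompound()].
#' @return The [summarizeSSRCounts()] list plus `n_unigenes_with_ssr`.
#' @export
summarizeSSRs <- function(motifs) {
  if (!"in_compound" %in% names(motifs)) {
    motifs$in_compound <- logical(nrow(motifs))
  }
  eff <- motifs[!motifs$in_compound, , drop = FALSE]
  simple <- eff[eff$nt_type != "compound", , drop = FALSE]
  byType <- integer(0)
  for (t in c(unname(.NT_TYPES), "compound")) {
    byType[t] <- sum(eff$nt_type == t)
  }
  byRepeat <- if (nrow(simple)) table(simple$repeats) else NULL
  byClass <- if (nrow(simple)) {
    sort(table(simple$class), decreasing = TRUE)
  } else NULL
  out <- summarizeSSRCounts(byType, byRepeat, byClass)
  out$n_unigenes_with_ssr <- length(unique(motifs$seq_id))
  out
}
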