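# Independent oracles: brute-force implementations used only to validate
# the package's algorithms on small inputs.

# ---- NG86 by exhaustive path recursion (no lookup tables) ----------------

oracleSynSitesCodon <- function(codon) {
  gc_ <- Biostrings::GENETIC_CODE
  if (gc_[codon] == "*") return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc_[mut] == gc_[codon]) s <- s + 1 / 3
    }
  }
  s
}

oracleCodonPairDiffs <- function(c1, c2) {
  gc_ <- Biostrings::GENETIC_CODE
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(c(sd = 0, nd = 0))
  acc <- list()
  walk <- function(cur, remaining, sd, nd, stopped) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- c(sd, nd, stopped)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- gc_[nxt] == gc_[cur]
      walk(nxt, setdiff(remaining, p), sd + syn, nd + !syn,
           stopped || (length(remaining) > 1L && gc_[nxt] == "*"))
    }
  }
  walk(c1, d, 0, 0, FALSE)
  m <- do.call(rbind, acc)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(sd = mean(m[keep, 1]), nd = mean(m[keep, 2]))
}

oracleNG86 <- function(cdsA, cdsB) {
  ca <- substring(cdsA, seq(1, nchar(cdsA), 3), seq(3, nchar(cdsA), 3))
  cb <- substring(cdsB, seq(1, nchar(cdsB), 3), seq(3, nchar(cdsB), 3))
  sA <- vapply(ca, oracleSynSitesCodon, 0)
  sB <- vapply(cb, oracleSynSitesCodon, 0)
  keep <- !is.na(sA) & !is.na(sB)
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(sA[keep]) + sum(sB[keep])) / 2
  N <- 3 * sum(keep) - S
  diffs <- vapply(seq_along(ca), function(i)
    oracleCodonPairDiffs(ca[i], cb[i]), c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  ks <- if (ps < 3 / 4) -3 / 4 * log(1 - 4 / 3 * ps) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, ks = ks)
}

randomSenseCodons <- function(n) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# ---- SSR scan by per-start greedy extension ------------------------------

oraclePrimitive <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        paste(rep(substr(unit, 1L, d), u / d), collapse = "") == unit) {
      return(FALSE)
    }
  }
  TRUE
}

oracleScanSSRs <- function(seq, thresholds = defaultSSRThresholds()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (u in 2:6) {
    thr <- thresholds[[as.character(u)]]
    if (L < u * thr) next
    nStart <- L - 2L * u + 1L
    if (nStart < 1L) next
    units <- substring(seq, 1:nStart, u:(nStart + u - 1L))
    nxt <- substring(seq, (1 + u):(nStart + u), (2 * u):(nStart + 2 * u - 1L))
    seeds <- which(units == nxt & !grepl("N", units))
    for (i in seeds) {
      unit <- units[i]
      if (!oraclePrimitive(unit)) next
      # leftmost start of this run
      if (i - u >= 1L && substring(seq, i - u, i - 1L) == unit) next
      k <- 2L
      while (i + (k + 1L) * u - 1L <= L &&
             substring(seq, i + k * u, i + (k + 1L) * u - 1L) == unit) {
        k <- k + 1L
      }
      if (k >= thr) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = i, end = i + k * u - 1L, unit = unit,
                     repeats = k)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), repeats = integer()))
  }
  df <- do.call(rbind, rows)
  ## a periodic region with a trailing partial unit yields shifted copies
  ## of the same run; keep only the leftmost phase
  df <- df[order(nchar(df$unit), df$start), , drop = FALSE]
  keepPhase <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keepPhase[i]) next
    for (j in seq_len(nrow(df))) {
      if (j == i || !keepPhase[j]) next
      u <- nchar(df$unit[i])
      if (nchar(df$unit[j]) == u && df$start[j] > df$start[i] &&
          df$start[j] - df$start[i] < u && df$start[j] <= df$end[i]) {
        keepPhase[j] <- FALSE
      }
    }
  }
  df <- df[keepPhase, , drop = FALSE]
  ul <- nchar(df$unit)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i != j && df$start[j] <= df$start[i] && df$end[j] >= df$end[i] &&
          ul[j] < ul[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, nchar(df$unit)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# A random background with no spontaneous SSR, certified by the oracle.
cleanBackground <- function(L, thresholds = defaultSSRThresholds()) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    if (nrow(oracleScanSSRs(s, thresholds)) == 0L) return(s)
  }
}

# ---- affine-gap global alignment score by dynamic programming ------------

oracleNWScore <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        sub[A[i - 1], B[j - 1]]
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext,
                     Y[i - 1, j] - (open + ext))
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext,
                     X[i, j - 1] - (open + ext))
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# ---- reciprocal best pairs by exhaustive search --------------------------

oracleRBH <- function(scores) {
  ids <- rownames(scores)
  diag(scores) <- NA
  bestOf <- function(g) {
    s <- scores[g, ]
    if (all(is.na(s))) return(NA_character_)
    sort(names(s)[!is.na(s) & s == max(s, na.rm = TRUE)])[1L]
  }
  out <- list()
  for (g in ids) {
    for (h in ids) {
      if (g < h && identical(bestOf(g), h) && identical(bestOf(h), g)) {
        out[[length(out) + 1L]] <- data.frame(gene_a = g, gene_b = h)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_a = character(), gene_b = character())
}

# ---- additive distance matrices from random trees ------------------------

randomAdditiveCase <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
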