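## Synthetic EST data with known truth: duplicated gene families at
## controlled synonymous divergence, planted SSR motifs, and
## accession-structured SNPs generated along a known tree.

## Per-codon synonymous single-base change options, cached.
.synOptCache <- new.env(parent = emptyenv())

#' @keywords internal
synonymousOptions <- function(codon) {
  opt <- .synOptCache[[codon]]
  if (!is.null(opt)) return(opt)
  gc_ <- Biostrings::GENETIC_CODE
  aa <- gc_[codon]
  res <- list()
  if (!is.na(aa) && aa != "*") {
    for (pos in 1:3) {
      for (b in setdiff(.BASES, substr(codon, pos, pos))) {
        c2 <- codon
        substr(c2, pos, pos) <- b
        if (gc_[c2] == aa) res[[length(res) + 1L]] <- c(pos, b)
      }
    }
  }
  opt <- if (length(res)) do.call(rbind, res) else
    matrix(character(), 0L, 2L)
  .synOptCache[[codon]] <- opt
  opt
}

#' Apply synonymous mutations to a coding sequence
#'
#' Draws `nMutations` single-base changes, each uniform over the synonymous
#' single-base changes available in the *current* sequence, applied
#' sequentially. The same site may be hit more than once, so realized
#' sequence differences can be fewer than `nMutations`; the amino-acid
#' sequence is invariant throughout.
#'
#' @param cds Stop-free coding sequence (length a multiple of 3).
#' @param nMutations Number of mutation events to apply.
#' @return The mutated nucleotide string.
#' @export
mutateSynonymous <- function(cds, nMutations) {
  codons <- splitCodons(cds)
  opts <- lapply(codons, synonymousOptions)
  cnt <- vapply(opts, nrow, 0L)
  if (sum(cnt) == 0L && nMutations > 0L) {
    stop("CDS hosts no synonymous single-base change")
  }
  for (m in seq_len(nMutations)) {
    i <- sample.int(length(codons), 1L, prob = cnt)
    o <- opts[[i]]
    k <- sample.int(nrow(o), 1L)
    cod <- codons[i]
    substr(cod, as.integer(o[k, 1L]), as.integer(o[k, 1L])) <- o[k, 2L]
    codons[i] <- cod
    opts[[i]] <- synonymousOptions(cod)
    cnt[i] <- nrow(opts[[i]])
  }
  paste(codons, collapse = "")
}

#' Simulate one duplicated gene family at a target Ks
#'
#' Draws a random stop-free ancestor CDS and a duplicate that differs only
#' at synonymous positions. The number of mutation events is Poisson with
#' mean `targetKs * S`, where S is the NG86 synonymous site count of the
#' ancestor, so the planted synonymous divergence is unbiased for the
#' target. Multiple hits at one site are allowed, which is what the
#' Jukes-Cantor correction of [computeKs()] later has to undo.
#'
#' @param params A [SimulationParams-class] object.
#' @param familyIndex 1-based family index; families cycle through
#'   `ksTargets` and each index has its own derived seed.
#' @return A list: `family`, `targetKs`, `ancestor`, `duplicate`,
#'   `realizedMutations`, `synSites`.
#' @examples
#' fam <- simulateDuplicatedFamily(SimulationParams(seed = 1), 1)
#' fam$targetKs
#' @export
simulateDuplicatedFamily <- function(params, familyIndex) {
  stopifnot(is(params, "SimulationParams"))
  targets <- params@ksTargets
  if (any(targets < 0)) stop("target Ks must be >= 0")
  target <- targets[(as.integer(familyIndex) - 1L) %% length(targets) + 1L]
  withSeed(deriveSeed(params@seed, familyIndex), {
    anc <- randomCds(params@cdsCodons)
    S <- synonymousSites(anc)
    if (S <= 0) stop("CDS too short to host a synonymous site")
    nMut <- if (target == 0) 0L else rpois(1L, target * S)
    dup <- if (nMut > 0L) mutateSynonymous(anc, nMut) else anc
    list(family = as.integer(familyIndex), targetKs = target,
         ancestor = anc, duplicate = dup,
         realizedMutations = nMut, synSites = S)
  })
}

#' Simulate a set of duplicated gene families
#'
#' @param params A [SimulationParams-class] object.
#' @return A list with `sequences` (a `DNAStringSet`; each family
#'   contributes `famNNN_a` and `famNNN_b`) and `truth`
#'   (`data.frame(family, gene_a, gene_b, target_ks, realized_mutations,
#'   syn_sites)`).
#' @export
simulateFamilies <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  fams <- lapply(seq_len(params@nFamilies), function(i) {
    simulateDuplicatedFamily(params, i)
  })
  ids <- sprintf("fam%04d", seq_along(fams))
  seqs <- character(2L * length(fams))
  seqs[c(TRUE, FALSE)] <- vapply(fams, `[[`, "", "ancestor")
  seqs[c(FALSE, TRUE)] <- vapply(fams, `[[`, "", "duplicate")
  names(seqs) <- as.vector(rbind(paste0(ids, "_a"), paste0(ids, "_b")))
  truth <- data.frame(
    family = seq_along(fams),
    gene_a = paste0(ids, "_a"),
    gene_b = paste0(ids, "_b"),
    target_ks = vapply(fams, `[[`, 0, "targetKs"),
    realized_mutations = vapply(fams, `[[`, 0L, "realizedMutations"),
    syn_sites = vapply(fams, `[[`, 0, "synSites")
  )
  list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Plant SSR motifs into a background sequence
#'
#' Inserts perfect tandem repeats at random, well-separated positions.
#' Insertion points are at least 10 bp apart so planted motifs cannot fuse
#' into a single longer run; spans are reported in the coordinates of the
#' returned (lengthened) sequence.
#'
#' @param sequence Background nucleotide string.
#' @param ssrSpec `data.frame(unit, repeats, count)`; units must be ACGT.
#' @param seed Integer seed.
#' @return A list: `sequence` (with insertions) and `spans`
#'   (`data.frame(start, end, unit, repeats)`, 1-based inclusive).
#' @examples
#' plantSSRs(strrep("ACGT", 50), data.frame(unit = "AG", repeats = 6,
#'                                          count = 1), seed = 1)$spans
#' @export
plantSSRs <- function(sequence, ssrSpec, seed = 1L) {
  sequence <- toupper(as.character(sequence))
  if (!nrow(ssrSpec)) {
    return(list(sequence = sequence,
                spans = data.frame(start = integer(), end = integer(),
                                   unit = character(), repeats = integer())))
  }
  if (any(grepl("[^ACGT]", ssrSpec$unit))) {
    stop("SSR units must contain only A, C, G, T")
  }
  inserts <- ssrSpec[rep(seq_len(nrow(ssrSpec)), ssrSpec$count), , drop = FALSE]
  withSeed(seed, {
    L <- nchar(sequence)
    nIns <- nrow(inserts)
    ## offsets after which to insert, pairwise >= 10 apart
    cand <- seq(1L, L - 1L, by = 10L)
    if (length(cand) < nIns) {
      stop("background too short to host ", nIns, " separated insertions")
    }
    off <- sort(sample(cand, nIns))
    ord <- sample.int(nIns) # random assignment of motifs to offsets
    motifs <- strrep(inserts$unit[ord], inserts$repeats[ord])
    pieces <- character(2L * nIns + 1L)
    spans <- data.frame(start = integer(nIns), end = integer(nIns),
                        unit = inserts$unit[ord],
                        repeats = as.integer(inserts$repeats[ord]))
    prev <- 0L
    shift <- 0L
    for (k in seq_len(nIns)) {
      pieces[2L * k - 1L] <- substr(sequence, prev + 1L, off[k])
      spans$start[k] <- off[k] + shift + 1L
      spans$end[k] <- spans$start[k] + nchar(motifs[k]) - 1L
      pieces[2L * k] <- motifs[k]
      shift <- shift + nchar(motifs[k])
      prev <- off[k]
    }
    pieces[2L * nIns + 1L] <- substr(sequence, prev + 1L, L)
    list(sequence = paste(pieces, collapse = ""), spans = spans)
  })
}

## Tips below each edge of a rooted phylo tree.
#' @keywords internal
edgeClades <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  ## edges in postorder: children before parents
  ord <- order(tree$edge[, 1L], decreasing = TRUE)
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2L]]])
}

#' Simulate multi-accession EST alignments with a SNP/SSR truth set
#'
#' For each unigene a random background is drawn, SSR motifs are optionally
#' planted, and SNP sites are placed by a single mutation on one branch of
#' the accession tree (chosen with probability proportional to branch
#' length), so every site is perfectly tree-compatible. Each accession then
#' contributes `coverage` EST reads per unigene, sampled as substrings with
#' N-noise. Alignment matrices share the unigene coordinate system: `-` is
#' a planted single-base deletion allele, `.` marks positions outside a
#' read.
#'
#' @param params A [SimulationParams-class] object.
#' @return An [ESTSimulation-class] object.
#' @examples
#' sim <- simulateAccessionAlignments(SimulationParams(seed = 1,
#'   nUnigenes = 3, nFamilies = 1))
#' sim
#' @export
simulateAccessionAlignments <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  tree <- params@accessionTree
  acc <- tree$tip.label
  if (params@coverage < 1L) stop("coverage must be >= 1")
  clades <- edgeClades(tree)
  elen <- tree$edge.length

  uids <- sprintf("UN%04d", seq_len(params@nUnigenes))
  unigenes <- character(params@nUnigenes)
  alignments <- vector("list", params@nUnigenes)
  names(alignments) <- uids
  memb <- list()
  truthSnps <- list()
  truthSsrs <- list()

  ## distribute planted SSR insertions across unigenes
  spec <- params@ssrSpec
  insUnigene <- integer(0)
  if (nrow(spec)) {
    total <- rep(seq_len(nrow(spec)), spec$count)
    insUnigene <- withSeed(deriveSeed(params@seed, 311L),
                           sample(params@nUnigenes, length(total),
                                  replace = TRUE))
  }

  for (u in seq_len(params@nUnigenes)) {
    su <- deriveSeed(params@seed, 1000L + u)
    res <- withSeed(su, {
      L <- max(300L, as.integer(round(rnorm(1, params@unigeneLengthMean,
                                            params@unigeneLengthSd))))
      bg <- paste(sample(.BASES, L, replace = TRUE), collapse = "")

      ssrRows <- NULL
      if (length(insUnigene)) {
        here <- which(insUnigene == u)
        if (length(here)) {
          idx <- rep(seq_len(nrow(spec)), spec$count)[here]
          sub <- data.frame(unit = spec$unit[idx],
                            repeats = spec$repeats[idx], count = 1L)
          pl <- plantSSRs(bg, sub, seed = deriveSeed(su, 7L))
          bg <- pl$sequence
          L <- nchar(bg)
          ssrRows <- cbind(unigene_id = uids[u], pl$spans)
        }
      }

      ## plant tree-consistent SNP sites
      bgChars <- strsplit(bg, "")[[1]]
      nSnp <- if (params@snpRate > 0) {
        sum(runif(L) < params@snpRate)
      } else 0L
      snpRows <- NULL
      hap <- matrix(rep(bgChars, length(acc)), nrow = length(acc),
                    byrow = TRUE, dimnames = list(acc, NULL))
      if (nSnp > 0L) {
        cols <- sort(sample.int(L, nSnp))
        branch <- sample.int(length(elen), nSnp, replace = TRUE,
                             prob = elen)
        isIndel <- runif(nSnp) < params@indelFraction
        anc <- bgChars[cols]
        derived <- character(nSnp)
        for (k in seq_len(nSnp)) {
          if (isIndel[k]) {
            derived[k] <- "-"
          } else if (runif(1) < params@transitionFraction) {
            derived[k] <- chartr("ACGT", "GTAC", anc[k]) # transition partner
          } else {
            tv <- setdiff(.BASES, c(anc[k], chartr("ACGT", "GTAC", anc[k])))
            derived[k] <- sample(tv, 1L)
          }
          hap[clades[[branch[k]]], cols[k]] <- derived[k]
        }
        snpRows <- data.frame(
          unigene_id = uids[u], column = cols, ancestral = anc,
          derived = derived,
          snp_class = vapply(seq_len(nSnp), function(k)
            classifySNP(anc[k], derived[k]), ""),
          derived_accessions = vapply(branch, function(b)
            paste(clades[[b]], collapse = ","), "")
        )
      }

      ## EST reads per accession
      reads <- list()
      for (a in acc) {
        for (r in seq_len(params@coverage)) {
          len <- min(L, max(50L, as.integer(round(
            rnorm(1, params@estLengthMean, params@estLengthSd)))))
          start <- sample.int(L - len + 1L, 1L)
          row <- rep(".", L)
          frag <- hap[a, start:(start + len - 1L)]
          if (params@nFraction > 0) {
            noise <- runif(len) < params@nFraction & frag != "-"
            frag[noise] <- "N"
          }
          row[start:(start + len - 1L)] <- frag
          reads[[sprintf("%s_%s_r%d", uids[u], a, r)]] <- row
        }
      }
      aln <- do.call(rbind, reads)
      list(bg = bg, aln = aln, snpRows = snpRows, ssrRows = ssrRows)
    })
    unigenes[u] <- res$bg
    alignments[[u]] <- res$aln
    if (!is.null(res$snpRows)) truthSnps[[length(truthSnps) + 1L]] <- res$snpRows
    if (!is.null(res$ssrRows)) truthSsrs[[length(truthSsrs) + 1L]] <- res$ssrRows
    ids <- rownames(res$aln)
    accOf <- sub("^UN\\d+_(.*)_r\\d+$", "\\1", ids)
    memb[[u]] <- data.frame(est_id = ids, unigene_id = uids[u],
                            accession = accOf)
  }

  names(unigenes) <- uids
  estSeqs <- unlist(unname(lapply(alignments, function(aln) {
    setNames(apply(aln, 1L, function(row) {
      paste(row[!(row %in% c(".", "-"))], collapse = "")
    }), rownames(aln))
  })))

  emptyS <- data.frame(unigene_id = character(), column = integer(),
                       ancestral = character(), derived = character(),
                       snp_class = character(),
                       derived_accessions = character())
  emptyR <- data.frame(unigene_id = character(), start = integer(),
                       end = integer(), unit = character(),
                       repeats = integer())
  new("ESTSimulation",
      params = params,
      unigenes = Biostrings::DNAStringSet(unigenes),
      alignments = alignments,
      ests = Biostrings::DNAStringSet(estSeqs),
      membership = do.call(rbind, memb),
      tree = tree,
      truthSnps = if (length(truthSnps)) do.call(rbind, truthSnps) else emptyS,
      truthSsrs = if (length(truthSsrs)) do.call(rbind, truthSsrs) else emptyR)
}

#' Write a simulated dataset to disk
#'
#' Emits one EST FASTA per accession, the unigene FASTA, the tab-delimited
#' cluster-membership table, one aligned FASTA per unigene, the truth
#' tables (1-based inclusive coordinates) and the accession tree as Newick.
#'
#' @param sim An [ESTSimulation-class] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(is(sim, "ESTSimulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "aligned"), showWarnings = FALSE)
  paths <- c()
  memb <- sim@membership
  for (a in unique(memb$accession)) {
    ids <- memb$est_id[memb$accession == a]
    p <- file.path(dir, paste0("est_", a, ".fasta"))
    Biostrings::writeXStringSet(sim@ests[ids], p)
    paths[paste0("est_", a)] <- p
  }
  p <- file.path(dir, "unigenes.fasta")
  Biostrings::writeXStringSet(sim@unigenes, p); paths["unigenes"] <- p
  p <- file.path(dir, "membership.tsv")
  writeTsv(memb, p); paths["membership"] <- p
  for (u in names(sim@alignments)) {
    writeAlignedFasta(sim@alignments[[u]],
                      file.path(dir, "aligned", paste0(u, ".afa")))
  }
  paths["aligned"] <- file.path(dir, "aligned")
  p <- file.path(dir, "truth_snps.tsv")
  writeTsv(sim@truthSnps, p); paths["truth_snps"] <- p
  p <- file.path(dir, "truth_ssrs.tsv")
  writeTsv(sim@truthSsrs, p); paths["truth_ssrs"] <- p
  p <- file.path(dir, "accession_tree.nwk")
  ape::write.tree(sim@tree, p); paths["tree"] <- p
  invisible(paths)
}
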