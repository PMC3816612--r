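## Distances from SNP genotype matrices, Saitou-Nei neighbor joining with
## deterministic tie-breaking, bootstrap supports, Newick IO.

#' Pairwise distances between accessions from a genotype matrix
#'
#' p-distance: the proportion of SNP sites at which two accessions carry
#' different alleles; the gap allele is a fifth state, so base-vs-gap
#' counts as a difference. Optionally Jukes-Cantor corrected
#' (`-3/4 log(1 - 4/3 p)`). p-distances need not satisfy the triangle
#' inequality.
#'
#' @param gm A complete [GenotypeMatrix-class] (no missing entries).
#' @param correction `"p"` (default) or `"jc"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   accession.
#' @export
pDistance <- function(gm, correction = c("p", "jc")) {
  correction <- match.arg(correction)
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!isComplete(gm)) stop("genotype matrix has missing entries")
  m <- alleleMatrix(gm)
  if (ncol(m) == 0L) stop("genotype matrix has zero sites")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(m[i, ] != m[j, ])
      if (correction == "jc") {
        if (p >= 3 / 4) stop("JC correction undefined for p >= 3/4")
        p <- -3 / 4 * log(1 - 4 / 3 * p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard agglomerative NJ: iteratively joins the pair minimizing the
#' Q-criterion, with branch lengths from the usual rate-corrected
#' formulas. Negative branch lengths are clamped to zero with the
#' remainder transferred to the sister edge, preserving the pair distance.
#' Ties in Q are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member tip), so the result
#' is deterministic. On an additive distance matrix the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labels
#'   (>= 3 taxa), e.g. from [pDistance()].
#' @return An unrooted `phylo` tree (basal trifurcation, as usual for NJ).
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' neighborJoining(d)$edge.length
#' @export
neighborJoining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  nodeId <- seq_len(n)            # ape ids of active clusters
  repName <- labels               # deterministic tie-break label
  nextInternal <- 2L * n - 2L     # filled downward; final node = n + 1
  edges <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  D <- d

  while (length(nodeId) > 3L) {
    m <- length(nodeId)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      p <- sort(c(repName[cand[k, 1L]], repName[cand[k, 2L]]))
      paste(p, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    newNode <- nextInternal
    nextInternal <- nextInternal - 1L
    edges <- rbind(edges, c(newNode, nodeId[i]), c(newNode, nodeId[j]))
    elen <- c(elen, li, lj)

    others <- setdiff(seq_len(m), c(i, j))
    newD <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newD),
               c(newD, 0))
    ids <- c(nodeId[others], newNode)
    reps <- c(repName[others], min(repName[c(i, j)]))
    rownames(D) <- colnames(D) <- NULL
    nodeId <- ids
    repName <- reps
  }

  ## final trifurcation at node n + 1
  a <- 1L; b <- 2L; cc <- 3L
  la <- (D[a, b] + D[a, cc] - D[b, cc]) / 2
  lb <- (D[a, b] + D[b, cc] - D[a, cc]) / 2
  lc <- (D[a, cc] + D[b, cc] - D[a, b]) / 2
  root <- n + 1L
  edges <- rbind(edges, c(root, nodeId[a]), c(root, nodeId[b]),
                 c(root, nodeId[cc]))
  elen <- c(elen, max(la, 0), max(lb, 0), max(lc, 0))

  tree <- list(edge = edges, edge.length = elen,
               tip.label = labels, Nnode = n - 2L)
  class(tree) <- "phylo"
  stats::reorder(tree, "cladewise")
}

## Non-trivial bipartitions of an unrooted tree, one per internal edge,
## canonicalized as the sorted tip set not containing the first tip label
## (alphabetically), collapsed to a string.
#' @keywords internal
treeBipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  allTips <- sort(tree$tip.label)
  anchor <- allTips[1L]
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  ord <- order(tree$edge[, 1L], decreasing = TRUE)
  for (e in ord) {
    desc[[tree$edge[e, 1L]]] <- c(desc[[tree$edge[e, 1L]]],
                                  desc[[tree$edge[e, 2L]]])
  }
  res <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= nt) next                       # trivial split
    tips <- desc[[ch]]
    if (length(tips) >= nt - 1L) next        # trivial complement
    side <- if (anchor %in% tips) setdiff(allTips, tips) else tips
    res <- c(res, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ch)
  }
  setNames(res, nodes)
}

#' Bootstrap supports for a neighbor-joining accession tree
#'
#' Builds the point-estimate NJ tree from the full genotype matrix, then
#' resamples SNP sites (columns) with replacement `replicates` times,
#' rebuilds the tree per replicate, and reports for each internal edge the
#' percentage of replicates containing that bipartition (integer percent,
#' stored as internal node labels). Deterministic given `seed`.
#'
#' @param gm A complete [GenotypeMatrix-class].
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @param correction Distance correction, as in [pDistance()].
#' @return A list: `tree` (`phylo` with `node.label` supports), and
#'   `splits` (`data.frame(bipartition, support)`).
#' @export
bootstrapSupport <- function(gm, replicates = 1000L, seed = 1L,
                             correction = "p") {
  stopifnot(is(gm, "GenotypeMatrix"), replicates >= 1L)
  main <- neighborJoining(pDistance(gm, correction))
  bip <- treeBipartitions(main)
  counts <- setNames(numeric(length(bip)), bip)
  m <- alleleMatrix(gm)
  sites <- snpSites(gm)
  withSeed(seed, {
    for (r in seq_len(replicates)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      g2 <- new("GenotypeMatrix", alleles = m[, idx, drop = FALSE],
                sites = sites[idx, , drop = FALSE])
      bt <- neighborJoining(pDistance(g2, correction))
      hits <- intersect(treeBipartitions(bt), bip)
      counts[hits] <- counts[hits] + 1
    }
  })
  support <- round(100 * counts / replicates)
  nt <- length(main$tip.label)
  lab <- rep("", main$Nnode)
  lab[as.integer(names(bip)) - nt] <- as.character(support)
  main$node.label <- lab
  list(tree = main,
       splits = data.frame(bipartition = bip,
                           support = as.integer(support),
                           row.names = NULL))
}

#' Write / read a tree as Newick
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; branch lengths
#' and internal node labels (bootstrap supports) survive the round trip.
#'
#' @param tree A `phylo` object.
#' @param file Path; `writeNewickTree(file = NULL)` returns the string.
#' @return The Newick string (write) or a `phylo` (read).
#' @export
writeNewickTree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname writeNewickTree
#' @param text Newick string (alternative to `file`).
#' @export
readNewickTree <- function(file = NULL, text = NULL) {
  if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
}
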