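## S4 containers for the simulation and the Ks / genotype results.

#' Simulation parameters for synthetic EST data
#'
#' Holds every tunable of the synthetic-data generator: duplicated gene
#' families at controlled synonymous divergence, accession-structured SNPs
#' generated along a known tree, planted SSR motifs, and EST fragmenting
#' with N-noise. Identical parameters and seed yield byte-identical output.
#'
#' @slot seed Integer master seed; all stage seeds derive from it.
#' @slot nFamilies Number of duplicated gene families to simulate.
#' @slot ksTargets Target synonymous divergence (Ks) per duplication event;
#'   families cycle through these targets.
#' @slot cdsCodons Codons per ancestral coding sequence.
#' @slot accessionTree Rooted `phylo` tree with branch lengths in expected
#'   substitutions/site; its tips are the accessions.
#' @slot snpRate Per-site probability that a unigene column carries a fixed
#'   difference between accessions.
#' @slot indelFraction Fraction of SNP sites planted as single-base gap
#'   columns rather than base substitutions.
#' @slot transitionFraction Probability that a substitution SNP is a
#'   transition (A<->G or C<->T).
#' @slot nUnigenes Number of unigene backgrounds for the accession
#'   simulation.
#' @slot unigeneLengthMean,unigeneLengthSd Unigene length distribution (bp).
#' @slot estLengthMean,estLengthSd EST fragment length distribution (bp).
#' @slot nFraction Probability that a read base is replaced by N.
#' @slot coverage EST reads per unigene per accession.
#' @slot ssrSpec `data.frame` with columns `unit`, `repeats`, `count`: SSR
#'   motifs to plant into unigene backgrounds.
#' @seealso [SimulationParams()], [simulateAccessionAlignments()]
#' @export
setClass("SimulationParams",
  representation(
    seed = "integer",
    nFamilies = "integer",
    ksTargets = "numeric",
    cdsCodons = "integer",
    accessionTree = "ANY",
    snpRate = "numeric",
    indelFraction = "numeric",
    transitionFraction = "numeric",
    nUnigenes = "integer",
    unigeneLengthMean = "numeric",
    unigeneLengthSd = "numeric",
    estLengthMean = "numeric",
    estLengthSd = "numeric",
    nFraction = "numeric",
    coverage = "integer",
    ssrSpec = "data.frame"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  probs <- c(snpRate = object@snpRate, indelFraction = object@indelFraction,
             transitionFraction = object@transitionFraction,
             nFraction = object@nFraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    msg <- c(msg, paste0("probabilities outside [0,1]: ",
                         paste(names(probs)[bad], collapse = ", ")))
  }
  counts <- c(nFamilies = object@nFamilies, cdsCodons = object@cdsCodons,
              nUnigenes = object@nUnigenes, coverage = object@coverage)
  if (any(counts < 1L)) {
    msg <- c(msg, paste0("counts must be positive: ",
                         paste(names(counts)[counts < 1L], collapse = ", ")))
  }
  if (any(object@ksTargets < 0)) {
    msg <- c(msg, "ksTargets must all be >= 0")
  }
  if (!inherits(object@accessionTree, "phylo")) {
    msg <- c(msg, "accessionTree must be an ape 'phylo' object")
  } else if (is.null(object@accessionTree$edge.length)) {
    msg <- c(msg, "accessionTree must carry branch lengths")
  }
  if (nrow(object@ssrSpec) &&
      !all(c("unit", "repeats", "count") %in% names(object@ssrSpec))) {
    msg <- c(msg, "ssrSpec needs columns unit, repeats, count")
  }
  if (length(msg)) msg else TRUE
})

#' Default accession tree: four cultivated and four wild radish accessions
#'
#' Mirrors the eight-accession design of the radish EST resource: four
#' *R. sativus* cultivars against four wild *R. raphanistrum* accessions,
#' with a deep cultivated/wild split. Branch lengths are expected
#' substitutions per site.
#'
#' @return An ape `phylo` tree with 8 tips.
#' @export
defaultAccessionTree <- function() {
  ape::read.tree(text = paste0(
    "(((RS_RatTail:0.02,RS_GSK31:0.02):0.015,",
    "(RS_EarlyScarlet:0.02,RS_Oleiformis:0.02):0.015):0.04,",
    "((RR_raphanistrumMS:0.02,RR_raphanistrumNY:0.02):0.015,",
    "(RR_maritimus:0.02,RR_landra:0.02):0.015):0.04);"
  ))
}

#' Construct simulation parameters
#'
#' Defaults emulate the structure of the radish EST study: Ks peaks planted
#' at 0.13 and 0.35 (300 families each), eight accessions split 4/4 into
#' cultivated and wild groups, unigene lengths around the reported 822 bp
#' average, and a SNP density of the order observed in the real data.
#'
#' @param seed Integer master seed.
#' @param nFamilies,ksTargets,cdsCodons Family simulation settings.
#' @param accessionTree ape `phylo`; see [defaultAccessionTree()].
#' @param snpRate,indelFraction,transitionFraction SNP planting settings.
#' @param nUnigenes,unigeneLengthMean,unigeneLengthSd Unigene backgrounds.
#' @param estLengthMean,estLengthSd,nFraction,coverage EST read settings.
#' @param ssrSpec `data.frame(unit, repeats, count)` of SSRs to plant.
#' @return A [SimulationParams-class] object.
#' @examples
#' p <- SimulationParams(seed = 1, nUnigenes = 5, nFamilies = 4)
#' p
#' @export
SimulationParams <- function(seed = 1L,
                             nFamilies = 600L,
                             ksTargets = c(0.13, 0.35),
                             cdsCodons = 300L,
                             accessionTree = defaultAccessionTree(),
                             snpRate = 0.008,
                             indelFraction = 0.13,
                             transitionFraction = 0.6,
                             nUnigenes = 100L,
                             unigeneLengthMean = 822,
                             unigeneLengthSd = 200,
                             estLengthMean = 600,
                             estLengthSd = 100,
                             nFraction = 0.01,
                             coverage = 3L,
                             ssrSpec = data.frame(unit = character(),
                                                  repeats = integer(),
                                                  count = integer())) {
  new("SimulationParams",
      seed = as.integer(seed), nFamilies = as.integer(nFamilies),
      ksTargets = as.numeric(ksTargets), cdsCodons = as.integer(cdsCodons),
      accessionTree = accessionTree, snpRate = snpRate,
      indelFraction = indelFraction, transitionFraction = transitionFraction,
      nUnigenes = as.integer(nUnigenes),
      unigeneLengthMean = unigeneLengthMean,
      unigeneLengthSd = unigeneLengthSd,
      estLengthMean = estLengthMean, estLengthSd = estLengthSd,
      nFraction = nFraction, coverage = as.integer(coverage),
      ssrSpec = ssrSpec)
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams\n")
  cat("  seed:", object@seed, "\n")
  cat("  families:", object@nFamilies, "at Ks targets",
      paste(object@ksTargets, collapse = ", "), "\n")
  cat("  accessions:", length(object@accessionTree$tip.label),
      "| unigenes:", object@nUnigenes,
      "| coverage:", object@coverage, "\n")
  cat("  snpRate:", object@snpRate, "| nFraction:", object@nFraction, "\n")
  invisible(NULL)
})

#' Synthetic multi-accession EST dataset with truth tables
#'
#' Produced by [simulateAccessionAlignments()]. Bundles the unigene
#' backgrounds, per-unigene alignment matrices, fragmented EST reads, the
#' cluster-membership table, and the truth tables (planted SNP sites and
#' SSR motifs) against which the miners are validated.
#'
#' @slot params The [SimulationParams-class] used.
#' @slot unigenes `DNAStringSet` of unigene background sequences.
#' @slot alignments Named list of character matrices (reads x columns);
#'   `-` is a gap allele, `.` marks no coverage.
#' @slot ests `DNAStringSet` of EST reads (gaps stripped).
#' @slot membership `data.frame(est_id, unigene_id, accession)`.
#' @slot tree The accession `phylo` tree.
#' @slot truthSnps `data.frame` of planted SNP sites (unigene, column,
#'   ancestral and derived alleles, class, derived accessions).
#' @slot truthSsrs `data.frame` of planted SSR spans.
#' @export
setClass("ESTSimulation",
  representation(
    params = "SimulationParams",
    unigenes = "ANY",
    alignments = "list",
    ests = "ANY",
    membership = "data.frame",
    tree = "ANY",
    truthSnps = "data.frame",
    truthSsrs = "data.frame"
  )
)

setValidity("ESTSimulation", function(object) {
  msg <- character()
  if (!all(object@membership$unigene_id %in% names(object@unigenes))) {
    msg <- c(msg, "membership refers to unknown unigenes")
  }
  if (nrow(object@truthSnps) &&
      !all(object@truthSnps$unigene_id %in% names(object@unigenes))) {
    msg <- c(msg, "truth SNPs refer to unknown unigenes")
  }
  if (nrow(object@truthSsrs) &&
      !all(object@truthSsrs$unigene_id %in% names(object@unigenes))) {
    msg <- c(msg, "truth SSRs refer to unknown unigenes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ESTSimulation", function(object) {
  cat("ESTSimulation:", length(object@unigenes), "unigenes,",
      length(object@ests), "EST reads,",
      length(object@tree$tip.label), "accessions\n")
  cat("  truth:", nrow(object@truthSnps), "SNP sites,",
      nrow(object@truthSsrs), "planted SSRs\n")
  invisible(NULL)
})

#' @describeIn ESTSimulation-class EST reads as a `DNAStringSet`.
#' @param x An `ESTSimulation`.
#' @export
estReads <- function(x) x@ests

#' @describeIn ESTSimulation-class Unigene backgrounds as a `DNAStringSet`.
#' @export
unigeneSeqs <- function(x) x@unigenes

#' @describeIn ESTSimulation-class Cluster membership table.
#' @export
estMembership <- function(x) x@membership

#' @describeIn ESTSimulation-class Per-unigene alignment matrices.
#' @export
alignmentMatrices <- function(x) x@alignments

#' @describeIn ESTSimulation-class Planted SNP truth table.
#' @export
truthSNPs <- function(x) x@truthSnps

#' @describeIn ESTSimulation-class Planted SSR truth table.
#' @export
truthSSRs <- function(x) x@truthSsrs

#' @describeIn ESTSimulation-class Accession tree (`phylo`).
#' @export
accessionTree <- function(x) x@tree

#' Accession-by-site SNP genotype matrix
#'
#' Rows are accessions, columns are SNP sites; entries are single symbols
#' from `A,C,G,T,-` or `NA` where an accession is uninformative. A
#' *complete* matrix (the input the accession phylogeny requires) has no
#' `NA` entries.
#'
#' @slot alleles Character matrix, accessions x sites, dimnames set.
#' @slot sites `data.frame(unigene_id, column, allele_pair, snp_class)`, one
#'   row per matrix column.
#' @seealso [buildGenotypeMatrix()], [pDistance()]
#' @export
setClass("GenotypeMatrix",
  representation(alleles = "matrix", sites = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  a <- object@alleles
  if (ncol(a) != nrow(object@sites)) {
    msg <- c(msg, "one site row per allele column required")
  }
  if (is.null(rownames(a))) msg <- c(msg, "accession rownames required")
  ok <- a %in% c("A", "C", "G", "T", "-") | is.na(a)
  if (!all(ok)) msg <- c(msg, "alleles restricted to A,C,G,T,- or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@alleles), "accessions x",
      ncol(object@alleles), "SNP sites;",
      if (isComplete(object)) "complete" else
        paste0(sum(is.na(object@alleles)), " missing entries"), "\n")
  invisible(NULL)
})

#' @describeIn GenotypeMatrix-class Allele matrix (accessions x sites).
#' @param x A `GenotypeMatrix`.
#' @export
alleleMatrix <- function(x) x@alleles

#' @describeIn GenotypeMatrix-class Site annotation table.
#' @export
snpSites <- function(x) x@sites

#' @describeIn GenotypeMatrix-class Accession names.
#' @export
accessionNames <- function(x) rownames(x@alleles)

#' @describeIn GenotypeMatrix-class `TRUE` when no entry is missing.
#' @export
isComplete <- function(x) !anyNA(x@alleles)

#' Ks distribution with detected density peaks
#'
#' Kernel density estimate of a sample of synonymous distances restricted to
#' (0, 3), with strict local maxima above a height floor reported as peaks —
#' the signature of whole-genome duplication events.
#'
#' @slot values The retained Ks values, all strictly inside (0, 3).
#' @slot x,y The density grid and heights.
#' @slot peaks `data.frame(ks, height)`, sorted by location.
#' @slot bandwidth Gaussian kernel bandwidth used.
#' @seealso [ksDensityPeaks()]
#' @export
setClass("KsDistribution",
  representation(values = "numeric", x = "numeric", y = "numeric",
                 peaks = "data.frame", bandwidth = "numeric")
)

setValidity("KsDistribution", function(object) {
  msg <- character()
  if (length(object@values) &&
      (min(object@values) <= 0 || max(object@values) >= 3)) {
    msg <- c(msg, "Ks values must lie strictly inside (0, 3)")
  }
  if (length(object@x) != length(object@y)) {
    msg <- c(msg, "density grid and heights differ in length")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KsDistribution", function(object) {
  cat("KsDistribution:", length(object@values), "Ks values, bandwidth",
      object@bandwidth, "\n")
  if (nrow(object@peaks)) {
    cat("  peaks at Ks =",
        paste(sprintf("%.3f", object@peaks$ks), collapse = ", "), "\n")
  } else {
    cat("  no peaks detected\n")
  }
  invisible(NULL)
})

#' @describeIn KsDistribution-class Detected peaks (`data.frame(ks, height)`).
#' @param x A `KsDistribution`.
#' @export
ksPeaks <- function(x) x@peaks

#' @describeIn KsDistribution-class Retained Ks values.
#' @export
ksValues <- function(x) x@values

#' Fossil-calibrated substitution rate interval
#'
#' A calibration split of known Ks and fossil age window (t_min, t_max)
#' million years bounds the synonymous substitution rate:
#' r in (Ks_cal / t_max, Ks_cal / t_min), in Ks per million years.
#'
#' @slot ksCalibration Ks of the calibration split.
#' @slot tInterval `c(t_min, t_max)` in million years.
#' @slot rInterval `c(r_min, r_max)` in Ks per million years.
#' @seealso [calibrateRate()], [dateEvent()]
#' @export
setClass("CalibratedRate",
  representation(ksCalibration = "numeric", tInterval = "numeric",
                 rInterval = "numeric")
)

setValidity("CalibratedRate", function(object) {
  msg <- character()
  r <- object@rInterval
  if (length(r) != 2L || any(r <= 0) || r[1] >= r[2]) {
    msg <- c(msg, "rate interval must be positive with r_min < r_max")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibratedRate", function(object) {
  cat(sprintf(
    "CalibratedRate: Ks %.3f over %.0f-%.0f MYA -> r in (%.5f, %.5f)/MY\n",
    object@ksCalibration, object@tInterval[1], object@tInterval[2],
    object@rInterval[1], object@rInterval[2]))
  invisible(NULL)
})

#' @describeIn CalibratedRate-class Rate interval `c(r_min, r_max)`.
#' @param x A `CalibratedRate`.
#' @export
rateInterval <- function(x) x@rInterval
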