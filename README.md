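# ESTevo

Comparative-genomic analysis of EST (expressed sequence tag) collections,
modelled on the radish (*Raphanus*) EST resource: marker mining, paralog-age
dating and accession phylogenetics, with a truth-tracked simulator so that
every stage can be validated end to end.

## What it does, and for whom

EST collections pooled from many cDNA libraries and accessions remain a
cheap substrate for three classic analyses, here implemented as one tested
R package for researchers working on crops with rich EST archives but
unfinished genomes:

1. **Quality filtering and assembly summaries.** Reads with more than 3% N
   bases are discarded; unigene (contig/singleton) membership distributions
   and consensus-length statistics are tabulated
   (`filterLowQuality()`, `membershipDistribution()`, `unigeneStats()`).

2. **SSR mining.** Perfect microsatellites with di- through hexa-nucleotide
   units at MISA-style thresholds (≥ 6 repeats for di-, ≥ 5 for tri- to
   hexa-), compound-motif merging, strand-canonical motif classes
   (TC/GA distinct from AG/CT), and flanking-sequence sufficiency for
   primer design (`scanSSRs()`, `mergeCompound()`, `summarizeSSRs()`,
   `checkFlanks()`).

3. **SNP calling.** From per-unigene multi-accession EST alignments, a
   column is a SNP when two accessions each show ≥ 2× coverage, are
   internally monomorphic, and share no base; calls are classified as
   transition (A↔G, C↔T), transversion, or single-base indel
   (`callSNPs()`, `classifySNP()`, `buildGenotypeMatrix()`).

4. **Ks distributions and WGD dating.** Within-species reciprocal-best
   paralog pairs are codon-aligned and their synonymous divergence
   estimated with the Nei–Gojobori (1986) method,

   Ks = −3/4 · ln(1 − 4/3 · pS),  pS = Sd/S,

   where S counts synonymous sites (averaged over both sequences) and Sd
   synonymous differences averaged over all minimal mutation paths between
   codons. Peaks of the Ks density (Gaussian kernel, values restricted to
   0 < Ks < 3) mark whole-genome duplications, dated through a
   fossil-calibrated rate interval r ∈ (Ks_cal/t_max, Ks_cal/t_min) via
   **T = Ks/r** (`computeKs()`, `ksDensityPeaks()`, `calibrateRate()`,
   `dateEvent()`).

5. **Accession phylogenetics.** p-distances over complete-information SNP
   genotype matrices, Saitou–Nei neighbor joining with deterministic
   tie-breaking, and column-resampling bootstrap supports
   (`pDistance()`, `neighborJoining()`, `bootstrapSupport()`).

The synthetic-data module (`SimulationParams()`, `simulateFamilies()`,
`simulateAccessionAlignments()`, `plantSSRs()`) generates gene families
duplicated at controlled synonymous divergence, EST fragments with N-noise,
planted SSR motifs, and accession-structured SNPs placed along a known
8-taxon tree with a cultivated/wild bipartition — so recall, precision and
parameter recovery can be measured against known truth.
`runPipeline()` orchestrates all stages from one YAML-style configuration
and writes a JSON manifest with output checksums; `generateDemo()` writes a
complete synthetic dataset.

## Worked example

```r
library(ESTevo)

params <- SimulationParams(seed = 42, nFamilies = 200, nUnigenes = 20,
                           ssrSpec = data.frame(unit = c("AG", "AAG"),
                                                repeats = c(7, 6),
                                                count = c(4, 4)))
sim <- simulateAccessionAlignments(params)
sim
#> ESTSimulation: 20 unigenes, 480 EST reads, 8 accessions
#>   truth: 126 SNP sites, 8 planted SSRs

motifs <- mergeCompound(scanSSRs(unigeneSeqs(sim)))
summarizeSSRs(motifs)$by_type
#>       di      tri    tetra    penta     hexa compound
#>        4        4        0        0        0        0

snps <- callSNPs(alignmentMatrices(sim), estMembership(sim))
gm <- buildGenotypeMatrix(snps)
gm
#> GenotypeMatrix: 8 accessions x 64 SNP sites; complete

bs <- bootstrapSupport(gm, replicates = 200, seed = 1)
head(bs$splits, 3)
#>                                         bipartition support
#> 1                               RS_GSK31|RS_RatTail     100
#> 2 RS_EarlyScarlet|RS_GSK31|RS_Oleiformis|RS_RatTail     100
#> 3               RR_raphanistrumMS|RR_raphanistrumNY      99
```

All eight planted SSRs are found (4 di- and 4 tri-nucleotide), the 64
fully-informative SNP sites recover the accession tree, and the
cultivated (`RS_*`) vs wild (`RR_*`) split carries 100% bootstrap support
(row 2: the four cultivars on one side).

Dating duplications from the same simulation's gene families:

```r
fams <- simulateFamilies(params)    # 200 pairs at Ks targets 0.13 / 0.35
ks <- apply(fams$truth, 1, function(r)
  computeKs(as.character(fams$sequences[[r[["gene_a"]]]]),
            as.character(fams$sequences[[r[["gene_b"]]]]))$ks)
kd <- ksDensityPeaks(ks, bandwidth = 0.03)
kd
#> KsDistribution: 200 Ks values, bandwidth 0.03
#>   peaks at Ks = 0.135, 0.351

dateEvent(ksPeaks(kd)$ks, calibrateRate(1.475, 54, 90),
          label = c("alpha", "beta"))
#>   label   ks_peak   t_young    t_old
#> 1 alpha 0.1352254  4.950624  8.25104
#> 2  beta 0.3505843 12.834951 21.39158
```

The two planted duplication waves are recovered as density peaks at
Ks ≈ 0.135 and 0.351; with the substitution rate bracketed by the 54–90 MY
Capparales fossil window (calibration Ks 1.475) they date to roughly 5–8
and 13–21 million years ago — the α and β duplication signatures the radish
EST data show.

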