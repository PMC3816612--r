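---
title: "EST marker mining and WGD dating: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EST marker mining and WGD dating: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ESTevo)
```

ESTevo reimplements, as one tested package, the analysis arc that EST
projects in crops such as radish follow: quality filtering and assembly
summaries, SSR and SNP marker mining, Ks-based whole-genome-duplication
(WGD) dating, and SNP-based accession phylogenetics. This vignette is the
package's account of the underlying models, the parameters that matter,
the numerical conventions, and the places where the design was genuinely
open.

## Quality filtering and assembly summaries

An EST is rejected when its N fraction *strictly exceeds*
`maxNFraction` (default 0.03): a 100 bp read with exactly 3 Ns passes.
N counting is case-insensitive; other IUPAC ambiguity codes are left
untouched — they are legitimate sequence, and the filter's mandate is
undetermined bases only. The filter assumes vector/adaptor trimming has
already happened upstream; no trimming is re-implemented.

Unigene statistics are computed over *consensus* lengths, not member-read
lengths, which is what published unigene tables report. The membership
distribution uses exact bins 1–10 and ranges 11–30, 31–50, 51–70, 71–90,
91–110, >110; for exact bins the EST column is `bin × n_unigenes` by
construction, an identity the reporter re-derives rather than trusts.
One arithmetic caveat the worked-example tests surface: in the published
radish membership table the unigenes with ≥ 10 members (6,404 of them)
hold 125,896 of 311,021 ESTs — a 40.48% share, which the source rounds
up to 41%; the acceptance checks therefore compare this share at
one-percentage-point slack while holding the two counts exactly.

## SSR mining

`scanSSRs()` reports every maximal perfect tandem run of a 2–6 bp unit
meeting its repeat threshold (defaults: 6 for di-nucleotide, 5 for tri-
through hexa-nucleotide — the thresholds of MISA-style EST screens).
Conventions that make the scan well-defined:

* runs are broken at N; a motif never contains an N;
* units that are repetitions of a shorter unit (`ATAT`) are not reported —
  the shortest-unit description wins, and a reported motif is never a
  sub-interval of another reported motif with a shorter-or-equal unit;
* a periodic region whose length is not an exact multiple of the unit
  admits several phase-shifted descriptions of the same run; the run is
  reported once, at its leftmost phase. A corollary used by the recovery
  tests: sequence flanking a planted repeat can extend the periodic
  region and shift the reported phase by up to unit − 1 bases, so
  planted-SSR recovery is scored by overlap, not exact span identity;
* scanning is single-strand; strand equivalence is handled at reporting
  time by `canonicalClass()`, which pairs a unit with its reverse
  complement *only* (TC/GA and AG/CT remain distinct classes, as SSR
  catalogues list them) — no rotational collapsing.

Compound SSRs merge consecutive motifs separated by at most `maxGap`
bases (default 100). The source material describes compounds as repeats
"separated by none to any number of base pairs"; taken literally that
would merge motifs across a whole unigene, so the default follows the
100 bp interruption convention of standard SSR screening tools, and
`maxGap = Inf` restores the literal behaviour. Because the published
compound count depends on an unstated interruption limit, that one count
is not exactly reproducible; the package treats it as configurable.
In summaries, a compound record replaces its constituents, so marginal
counts always sum to the total.

`checkFlanks()` implements only the flank-sufficiency predicate
(≥ `minFlank` = 50 non-N bases each side) that primer design needs;
primer design itself is out of scope.

## SNP calling

The caller operates directly on per-unigene alignment columns. A column
yields a SNP for an accession pair when each accession has at least
`minCoverage = 2` non-N observations, each is internally monomorphic, and
the two observed bases differ; a gap against a base is a single-base
indel. Classification is the textbook partition: A↔G and C↔T are
transitions, other base pairs transversions, gap pairs indels.

Interpretation choices: internal monomorphism is required (an accession
showing two bases at a site is unresolved there — with ESTs pooled per
accession there is no heterozygote model to appeal to); N observations
never count toward coverage; a site supported by several accession pairs
is emitted once; and indel calls inside gap runs longer than one column
are discarded, since only single-base indels are scored. The caller is a
direct implementation of these filters — no base-quality or Bayesian
pre-screen stands in front of them, because on EST data it is these
coverage/fixed-difference filters that define a high-quality SNP.

`buildGenotypeMatrix(requireComplete = TRUE)` keeps only sites informative
in *every* accession — the "complete information" subset that distance
phylogenetics needs.

## Ks distributions and WGD dating

Paralog pairs come from reciprocal best hits on global protein alignment
scores (BLOSUM62, gap open 10, extend 0.5). At scale the all-vs-all is
preceded by a k-mer cosine prefilter (`topN = 3` candidates per gene)
before exact alignment — playing the role a BLAST E-value screen plays in
database-scale pipelines. Redundant CDS (alternative splicing, cross
sub-species duplicates) are removed beforehand by three rules: alignment
> 600 bp at > 95% amino-acid identity; both CDS < 600 bp with alignment
> 300 bp at > 95% identity; or aligned coverage ≥ 95% of either member at
≥ 95% identity (the asymmetric ≥ in the third rule is deliberate — the
rules are implemented as stated, not harmonized). The shorter member is
always the one removed; pairs are processed by descending identity with
greedy removal, which makes cascades order-independent.

Translation uses the longest stop-free ORF across six frames with a
100-amino-acid floor, with no ATG requirement — appropriate for partial
cDNA, where the true start is often upstream of the read. A
matrix-trained HMM translator would need an external training set; the
longest-ORF rule is deterministic and self-contained.

Ks itself is Nei–Gojobori (1986) with Jukes–Cantor correction:
synonymous site counts average the two sequences (changes creating stop
codons count as nonsynonymous, so S + N = 3 × codons always); difference
counts average over all minimal mutation paths between codon pairs,
excluding paths through stop codons; and
Ks = −3/4·ln(1 − 4/3·pS), undefined (flagged, excluded downstream) when
pS ≥ 3/4. The estimator is deliberately the closed-form countable one: it
can be verified to 1e-9 against an independent path-enumeration oracle,
which a maximum-likelihood F3×4 codon model cannot. For the quantity used
downstream — peak *location* — the choice is immaterial at the tested
divergences.

A known property the tests quantify rather than hide: under the
simulator's mutation model, two-fold degenerate sites saturate at
difference probability 1/2 while the Jukes–Cantor inversion assumes 3/4,
so the estimator acquires a small upward offset as divergence grows —
negligible at Ks ≈ 0.13 (the Monte-Carlo mean is within 3 SE of target)
and about +0.015 at Ks ≈ 0.35, well inside the ±0.05 peak tolerance used
for recovery.

Peak detection fits a Gaussian kernel density (bandwidth 0.03, 600-point
grid) over Ks ∈ (0, 3) — the standard admissible range for paralog-age
distributions — and reports strict local maxima above 10% of the global
maximum. No smoothing prescription exists in the source material; these
defaults resolve peaks 0.1 apart while suppressing sampling ripple, and
all three knobs are exposed.

Dating uses T = Ks/r with the rate bracketed by a fossil window:
r ∈ (Ks_cal/t_max, Ks_cal/t_min), default window 54–90 MY (the Capparales
fossil interval). The calibration Ks is a required input, because the
source material never prints it; the demo and acceptance default of
**1.475** is the value consistent with the published age intervals — a
Ks-0.35 peak dated 12.8–21.4 MYA implies Ks_cal ≈ 1.47 at both window
endpoints. (The published α interval of 5.1–8.4 MYA implies a peak near
0.138 rather than exactly 0.13; the package dates whatever peak it
detects and leaves that tension alone.)

## Neighbor joining and bootstrap

Distances are p-distances over SNP alleles (the gap allele is a fifth
state: indel SNPs are first-class markers), with a Jukes–Cantor-corrected
alternative; p-distances may violate the triangle inequality, which NJ
does not require. The NJ join loop is the standard Saitou–Nei Q-criterion
with the usual branch-length formulas; negative estimates are clamped to
zero with the remainder moved to the sister edge so the pair distance is
preserved (the convention of mainstream phylogeny software). Q-ties are
broken by the lexicographically smallest pair of cluster labels, making
the tree — and therefore bootstrap supports — fully deterministic given a
seed. On additive matrices the algorithm recovers topology and branch
lengths exactly, which the tests exercise over random trees of up to 12
taxa. Bootstrap resamples SNP columns with replacement, rebuilds the tree
per replicate, and reports integer-percent support per internal
bipartition of the point-estimate tree.

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions of the radish EST
resource: 600 duplicated families split over Ks targets 0.13 and 0.35
(the two duplication waves), eight accessions in a 4 + 4
cultivated/wild tree, unigene lengths around the reported 822 bp mean,
~0.008 per-site SNP density (the order implied by 28,758 SNPs in 4,764
unigenes), 13% of SNPs as single-base indels and a 60% transition share
(Table-4 proportions), EST fragments of 600 ± 100 bp at 3× per-accession
coverage with 1% N-noise.

Mechanics: duplicates diverge by a Poisson number of mutations (mean
target-Ks × S) drawn uniformly over the synonymous single-base changes of
the current sequence — multiple hits allowed, so the Jukes–Cantor
correction is exercised realistically, while the amino-acid sequence is
invariant by construction. SNP sites arise from a single mutation on one
tree branch (probability proportional to branch length), so every site is
perfectly tree-compatible. Planted SSR insertions are kept ≥ 10 bp apart
so two planted repeats cannot fuse.

Deliberate omissions, hence limits on what green tests prove about real
data: no sequencing-error substitutions (noise is N-only, so caller
precision on synthetic data is structurally 1), no indel evolution along
the tree, no selection or rate heterogeneity, no homoplasy, no chimeric
or misassembled unigenes, uniform base composition. Real EST data violate
all of these; the synthetic suite validates the *algorithms*, not the
error robustness of the full observational process.

## Reproducibility and problem sizes

Every stochastic component takes a seed; per-family and per-stage streams
are derived from one master seed, and identical configuration plus seed
reproduces outputs byte-for-byte (the pipeline manifest records MD5
checksums to make this checkable). The validation suite sizes were chosen
to give tight Monte-Carlo error at interactive runtimes: 500 replicates
for unbiasedness checks, 600 families for peak recovery, 1,000 random
alignments/sequences for the NG86 and SSR oracle-equivalence sweeps, 200
random trees for NJ exactness, and 200 bootstrap replicates (supports are
percentages; 200 resolves the ≥ 95 question) — against 1,000 in the
original study design, where the extra replicates buy nothing but
resolution below one percentage point.
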