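---
title: "Profiling repeat-based centromeres from low-pass reads and fluorescence profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling repeat-based centromeres from low-pass reads and fluorescence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroscope)
```

## The problem

In many species the centromere is defined epigenetically by the
centromere-specific histone H3 variant (CenH3/CENP-A) rather than by a
conserved DNA sequence, and the DNA it sits on is highly repetitive
satellite DNA that is typically missing from the genome assembly.  The
red flour beetle is an extreme case: roughly a fifth of its ~204-Mb
genome — essentially the (peri)centromeric repeats, dominated by a
360-bp-monomer major satellite comprising ~17% of the genome in five
subfamilies diverged by up to 30% — is absent from the assembly.
Assembly-based ChIP-seq analysis is therefore impossible, and the
standard workaround is assembly-free:

1. cluster low-pass (well below 1x) unassembled WGS reads into *repeat
   clusters* by graph-based sequence similarity; a cluster's read share
   estimates its genome proportion;
2. map CenH3-ChIP reads and matched input (pre-immunoprecipitation)
   reads onto the leading clusters by similarity search and score each
   cluster by its ChIP/input hit ratio;
3. select centromere-candidate clusters by dual criteria that balance
   enrichment against abundance;
4. independently, quantify centromere extent and CenH3/satellite
   co-localization from fluorescence intensity profiles measured along
   chromosomes and extended chromatin fibers.

`centroscope` implements this whole chain at desk scale, together with a
synthetic repeatome generator that provides exact ground truth for every
stage, so each algorithm can be validated by parameter recovery rather
than by eyeballing.

## The synthetic repeatome

`genome_spec()` + `build_genome()` produce monocentric chromosomes with
one centromere interval per chromosome covering a configurable fraction
of its length (default 0.435, the cytological average reported for the
extended beetle centromeres this generator emulates).  Families are
planted per `repeat_family_spec()`:

* tandem families as head-to-tail monomer arrays; centromeric families
  inside the centromere interval, with 20% of their arrays placed
  immediately adjacent to it (pericentromeric spill-over, mimicking
  satellite arrays that outspread beyond the CenH3 domains);
* dispersed families as isolated copies in the arms;
* the rest as i.i.d. uniform background.

Subfamily consensuses are built by mutating one random ancestor monomer
at distinct uniformly chosen positions (substitutions only — no indel
model is assumed).  Subfamily *i* of *n* diverges from the ancestor by
`max_divergence / 2 * (i - 1) / (n - 1)`, which bounds every pairwise
divergence by `max_divergence` while the extreme pairs approach it.
This ladder also makes nearby subfamilies nearly indistinguishable at
read length, so clustering merges them — reproducing the observation
that no cluster corresponds to a single satellite subfamily.

The default family set (`tribolium_like_families()`) fixes the study
conditions: major satellite 360 bp / 17% / 5 subfamilies / 30%
divergence, centromeric; a ~180-bp euchromatic minor satellite at 0.5%;
a 73-bp centromeric satellite at 0.05%; a 192-bp 5S rDNA unit (119-bp
gene + 73-bp spacer); dispersed 1.2-kb retroelement-like copies at 5%;
and short (~250 bp) interstitial TCAGG-like arrays.  Free parameters
that the emulated study does not pin down were chosen once: the 20%
spill-over fraction, the ~3-kb default array size, the 0.2% 5S fraction,
and the 350-bp paired-end fragment size.

ChIP reads are simulated under an explicit occupancy model
(`occupancy_model()`): read starts inside an *occupied* centromeric
array of a weighted family are drawn with the family weight, everything
else with the background weight, and only a fraction of a family's
centromeric arrays are occupied.  Partial occupancy is the mechanism by
which a highly abundant centromeric satellite can show only modest ChIP
enrichment, and the closed-form expected enrichment
(`expected_family_enrichment()`) makes that quantitative: with weight 4,
occupancy 0.5 and ~17% satellite content the family-level expectation is
about 1.8 — below the 2-fold "enriched" bound but far above 1, which is
exactly why the dual selection criteria include a high-abundance block.

What the generator does **not** emulate: sequencing errors beyond an
optional uniform substitution rate, indels, PCR duplicates, adapter
contamination, copy-level satellite homogenization structure
(higher-order repeats), or the real satellite sequences.  Passing
recovery tests therefore demonstrates correctness of the algorithms
under idealized read models, not performance on real libraries.

## Preprocessing

`quality_filter()` keeps reads in which at least 95% of bases reach
Phred 10 (both bounds inclusive); `trim_to_length()` enforces a uniform
151-nt length by 3'-truncation and drops shorter reads;
`interlace_pairs()` orders intact pairs mate1/mate2 and drops orphaned
mates (clustering consumes interlaced intact pairs);
`subsample_to_coverage()` draws `ceiling(coverage * genome / read
length)` reads — rounded up to even for paired input, sampled by pair —
and warns outside the 0.01–0.50x band recommended for repeat discovery.
The rounding rule reproduces the canonical census: 0.2x of 204 Mb at
151 nt is 270,200 reads.

## Graph-based clustering

Two reads are joined by an edge when their best local alignment, in
either orientation, reaches identity ≥ 0.90 over ≥ 0.55 of the read
length.  The contract is exhaustive all-vs-all alignment; the
implementation prefilters candidate pairs by shared canonical k-mers
(k = 10 by default) and the suite verifies equivalence against the
exhaustive mode and against an independent brute-force oracle built on
`Biostrings::pairwiseAlignment`.  Alignment uses Smith–Waterman with
match +1, mismatch −2 and linear gap −3 (compiled code); identity is
matches over alignment columns.  One numerical caveat: when several
local alignments of a pair are co-optimal, different implementations can
report column counts differing by one, so pairs sitting exactly on a
threshold may be classified either way; clusters are unaffected and the
oracle comparison allows such boundary ties.

Clusters are connected components with ≥ 2 members — at desk scale
components are sufficient and deterministic, so no community-detection
refinement is attempted — ranked CL1, CL2, … by descending size with
lexicographic tie-breaks.  Everything downstream treats the full member
read set (not a consensus) as the cluster reference, matching
similarity-based mapping of ChIP reads against clusters.

## Enrichment scoring and selection

`map_reads_to_clusters()` assigns each ChIP/input read at most one hit:
to the cluster holding its best-scoring member match with local
alignment bit score ≥ 90 (the middle of the commonly tested 30/90/150
ladder), ties to the more abundant cluster.  Bit scores are
`(λS − ln K)/ln 2` with the ungapped Karlin–Altschul parameters for
+1/−2 scoring (λ = 1.28, K = 0.46).  One-hit-per-read counting keeps
counts ≤ library size and ratios library-size invariant.

`compute_enrichment()` forms per-cluster ChIP/input ratios for equally
sized libraries (zero input ⇒ ratio undefined, reported NA, never
infinity), `mean_enrichment()` takes the arithmetic mean of the defined
per-cluster ratios, and `select_candidates()` applies the dual criteria
with strict ratio bounds:

* **high-abundance**: ratio > 1 and ChIP hits > 1% of analyzed reads;
* **enriched**: ratio > 2 and ChIP hits ≥ 0.01% of analyzed reads.

A cluster satisfying both goes to the high-abundance block by default
(`precedence` in `mapper_config()` flips this), mirroring how published
selections tabulate such clusters.  `subfamily_proportions()` decomposes
a satellite cluster by assigning each member to its best-scoring
subfamily consensus, with lexicographic tie-breaks and an unassigned
bucket below 70% identity.

## Cytometry from line profiles

The package starts from extracted 1-D line profiles (the "plot profile"
output of image software), not from images.  `threshold_profile()`
implements the isodata iterative-intermeans algorithm — the algorithm
behind ImageJ's default auto-threshold — plus a fixed-threshold mode;
presence is intensity strictly above the threshold.  (A presence rule of
"≥ 0" would mark every pixel present; strict positivity is the working
interpretation, and the threshold is exposed as a parameter.)

`detect_domains()` calls maximal present runs after bridging gaps below
`min_gap` and dropping runs below `min_domain`; the defaults (2% and 1%
of the chromosome length) are free parameters, chosen so that the
four-domain bead-like pattern with gaps of several percent survives
while single-pixel noise does not.  `centromere_measurement()` defines
centromere length as the distance between the *outer* edges of the first
and last CenH3 domain — the inclusive reading, since the exclusive one
would measure dot-like single-domain centromeres as zero — and reports
it relative to the DNA-stain span, making the ratio invariant to
uniform coordinate rescaling.  `overlap_fraction()` quantifies
two-channel co-localization as co-positive positions over the union of
positive positions (the signal-bearing span of the measured fiber);
it is symmetric and bounded by each channel's own fraction.

## CPM normalization

`cpm()` is `hits / library size × 10^6`; `aggregate_cpm()` averages CPM
over sequencing runs within each biological replicate and only then
takes mean and sample SD across replicates, keeping the replicate as
the error unit (the design behind expression bar plots with replicate
error bars).  Pooling runs would understate replicate variance, which is
why the two-stage average is not optional.

## Numerical and design choices

* Rounding for reported ratios is half-up to 2 decimals
  (`round_half_up()`); full precision is kept internally.
* All tie-breaks (cluster ranks, subfamily assignment, mapper hits) are
  deterministic and documented, so runs reproduce bit-for-bit from the
  global seed; per-stage seeds derive as `seed * 64 + stage index`.
* On-disk intervals are BED (0-based half-open); in memory coordinates
  are 1-based inclusive.
* Read counts round *up* (to even, for pairs) so coverage targets are
  never undershot.
* Degenerate inputs signal rather than guess: all-zero occupancy
  weights, empty cluster lists, profiles with no signal, undefined
  means.

## Problem sizes

The suite and the acceptance script run everything on reduced problem
sizes chosen to exercise each code path while staying desk-scale: a
2-Mb, two-chromosome genome at 0.2x coverage (2,650 clustering reads)
with 20,000-read ChIP/input libraries for end-to-end recovery; 200
reads for the brute-force clustering oracle; 500 reads for subfamily
recovery; 240 simulated chromosomes and single fibers for cytometry.
The published genome-scale numbers that depend on the real 204-Mb read
data (cluster censuses, hit tables, cytological averages) are checked
as exact arithmetic on their printed inputs instead.

## Limitations

Cluster counts and clustered fractions on synthetic genomes are not
comparable to real-genome values (real repeat landscapes are vastly more
diverse); the mapper's k-mer candidate cap is a heuristic whose
exhaustive setting (`max_candidates = 0`) defines the contract; and the
bit-score calibration assumes the ungapped score statistics, which is
adequate for thresholding near-exact repeat matches but not for remote
homology.
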