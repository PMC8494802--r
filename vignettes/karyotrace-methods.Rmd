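---
title: "Haplotype-resolved copy number and karyotype histories in cleavage-stage embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved copy number and karyotype histories in cleavage-stage embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotrace)
```

## The problem

A CRISPR-Cas9 double-strand break splits a chromosome into a centric and
an acentric fragment. If the break persists into mitosis, the acentric
fragment can missegregate (a reciprocal gain/loss between sister
blastomeres, with loss of heterozygosity in the losing cell), be trapped
in a micronucleus where it replicates poorly, or — after sister-chromatid
fusion — form a dicentric bridge whose resolution leaves one daughter with
all copies of the cut homolog and its sister monosomic. In a hybrid
C57BL/6J x 129/SvJae cross, every read can be assigned to a parental
haplotype through strain-specific SNPs, which turns noisy single-cell
total copy number into clean integer per-haplotype karyotypes and lets the
history of the first three cleavage divisions be reconstructed from the
8-cell stage.

`karyotrace` implements that analysis end to end — depth normalization,
replication-timing correction, circular binary segmentation, SNP panel
selection, VAF-based ploidy estimation, haplotype decomposition,
structural-variant joint genotyping, and a rule-based event classifier —
together with a lineage simulator that generates sequencing-like
observables from implanted events, so every stage is validated against
ground truth without any sequencing data.

## The depth model

Read counts are collected in 10 kb native bins, re-binned to 50 kb (the
most granular analysis level; 250 kb for ~0.15X low-pass libraries where
50 kb is too noisy). Each sample is divided by its own median across all
bins, so relative copy number has per-sample median exactly 1; samples
with zero median are dropped. Bins whose normalized coverage falls below
25% of the genome-wide median in more than 80% of samples are masked from
every downstream statistic. Aggregation to the analysis resolution
(250 kb to 5 Mb) averages unmasked constituents and then divides each bin
by its cross-sample median to cancel locus-specific coverage bias.

Two properties of median normalization are worth knowing. First, in an
aneuploid cell the per-sample median sits at a shifted quantile of the
modal copy-number cluster, biasing all relative values by a fraction of
the bin-level noise; the bias is negligible when altered regions are a
small fraction of the genome (as for any single mouse chromosome) but
visible on very small toy genomes. Second, the cross-sample median is a
cohort statistic: computed within a single 8-cell embryo it will absorb
any alteration shared by all blastomeres (e.g. a meiotic trisomy). The
package therefore lets the locus median be taken from reference (euploid)
samples, the panel-of-normals idiom; the validation suite does exactly
that when testing recovery of meiotic events.

A subset of amplified single-cell libraries carries a coverage bias that
tracks replication timing. `correct_replication_timing()` fits, per
sample, a robust LOESS (span 0.3 of points, degree 1) of bin CN on the
timing statistic over unmasked bins and divides it out, re-centering to
median 1. We fit per sample rather than pooled because the bias strength
is a per-library property. A constant track triggers an identity
transform with a warning. Because the regression conditions on a genomic
covariate, a copy-number alteration co-extensive with a large fraction of
the genome can be partially absorbed; with events confined to a
chromosome arm the correction is near-identity away from the bias (the
suite checks |r| < 0.05 after correction and preservation of a 1.5x
segment).

## Segmentation

Copy number is segmented by circular binary segmentation: recursively,
the arc of bins whose mean differs most from its complement (the circular
max-t statistic, computed in C++ over all O(n^2) arcs with prefix sums)
is tested and, if significant, its boundaries become change-points; ties
break toward the leftmost coordinate, and segments always tile the
chromosome even across masked bins. Two p-value routes are provided:

* `gaussian` (default): the statistic is standardized by a chromosome-wide
  robust noise scale (median absolute lag-one difference / sqrt(2),
  estimated once and reused at every recursion level) and referred to a
  Bonferroni-corrected t tail whose degrees of freedom reflect that
  estimate. An exactly piecewise-constant vector has zero robust scale
  and always splits — so noiseless steps are recovered at any length.
* `perm`: the classical permutation p-value with early termination once
  non-significance is certain. On very short vectors the permutation
  distribution is too coarse to reach small significance levels (a
  perfect 3+3 step admits p ~ 0.07 at best), which is why the default is
  the analytic route; the two agree on clear change-points at moderate n.

Defaults are alpha = 0.01, minimum segment width 2 bins, 1000
permutations. On vectors of up to 12 bins the default route is verified
against an exhaustive least-squares oracle (all breakpoint sets, RSS plus
a per-breakpoint penalty) on a fixed random battery.

Sample QC follows the noise of the final CN profile: a sample passes when
the MAD of its unmasked bin CN is at most 0.15 (low-pass regime, 250 kb
bins) or 0.3 (deep regime, 50 kb bins); both thresholds are configurable.

## Haplotypes and ploidy

Strain-informative SNPs (reference allele C57BL/6J, alternate 129/SvJae)
are selected by the across-sample median VAF falling in the closed window
[0.40, 0.60]; the median is taken over samples with nonzero depth only
(low-pass libraries leave most sites uncovered in any one cell) and a
site must be covered in at least 3 samples before the median is trusted.
With ~9X per cell the per-sample VAF at a single SNP is coarse, so the
window test only stabilizes at cohort scale — the suite pools 48
blastomeres for that check. In simulations the cross panel is a known
input of the generator, so downstream stages are tested against the true
panel while panel *selection* is tested on cohorts.

Bin VAF uses two-level aggregation: allelic depths are first averaged
over SNPs within 5 kb micro-bins (so clusters of SNPs with correlated
coverage carry the weight of one locus), micro-bin averages are summed
across the CN bin, and VAF = alt / (alt + ref). Ploidy is then estimated
from the genome-wide mean bin VAF: if 1 / min(VAF, 1 - VAF) lies in the
closed window [2.5, 3.5] the sample is called triploid and its copy
numbers multiplied by 1.5; otherwise it is assumed diploid. Values beyond
the window (which a tetraploid or haploid genome could produce) are
deliberately not extrapolated: the sample is treated as diploid with a
logged note. Within an embryo, blastomeres whose call disagrees with the
modal ploidy are flagged and excluded from event inference; a tie leaves
the embryo indeterminate.

Haplotype copy number is `VAF x total CN` (129/SvJae) and
`(1 - VAF) x total CN` (C57BL/6J), with total CN scaled so a balanced
diploid bin reads (1, 1). Segment-level haplotype means weight member
bins by their SNP count, which is unbiased under missing-VAF bins. A
segment is flagged `half_copy` — the micronucleus underreplication
signature at a G2 harvest — when one haplotype mean is within 0.15 of a
half-integer while the other is within 0.15 of an integer; the tolerance
is our choice and is configurable.

## Event classification

Per blastomere, segment haplotype means are rounded against the expected
baseline (one copy per haplotype, or two maternal copies in a digynic
embryo) and mapped to: whole-chromosome monosomy/trisomy, distal
(acentric-side) gains and losses starting at a breakpoint, centric-side
surplus, and the half-copy micronucleus signature. Breakpoints within a
configurable tolerance of the Cas9 cut are flagged on-target; "arm-level"
is operationalized as a segment spanning at least 30% of its chromosome.
Embryo-level rules then combine blastomeres:

* reciprocal acentric gains and losses of the same haplotype segment are
  paired, and the balanced group size gives the division (4+4 blastomeres
  = division 1, 2+2 = division 2, 1+1 = division 3); unbalanced groups
  (missing blastomeres) degrade to a division range with an ambiguity
  flag rather than a point estimate;
* a whole-chromosome zero-copy haplotype plus a sibling carrying surplus
  (>= 2) copies of that haplotype's centric portion is called a
  dicentric-bridge monosomy, with the division inferred from the number
  of monosomic blastomeres; monosomy without sibling surplus stays
  unclassified for review;
* a whole-chromosome gain of the same haplotype in every QC-passing
  blastomere is a meiotic trisomy, and genome-wide 2:1
  maternal:paternal dosage with triploid calls in all blastomeres is
  digyny — both predate the zygote.

The classifier emits the most parsimonious event set; where rules admit
alternatives it attaches flags instead of silently choosing.

## The simulator

`simulate_embryo()` grows a zygote through three divisions and applies
events to a chosen mother cell; daughters receive the mechanistic
outcomes described above, and meiotic events modify the zygote. All
chromosomes are telocentric (centromere at coordinate 0, as in the
mouse), so the centric fragment of a cut at x is [0, x) and the acentric
fragment [x, length). Coordinates are 0-based half-open everywhere.

Observables are generated from the realized karyotypes. Expected bin
counts are proportional to harvested DNA mass — at a G2 harvest each
replicated copy contributes two mass units and each micronucleated
(unreplicated) copy one, which is what makes the acentric fragment read
~0.5 copies relative to its replicated centric partner — times coverage
depth, bin width, an optional per-bin bias profile and an optional
replication-timing modulation. Counts are negative binomial; the paper's
data do not identify a count-noise family, so the NB with per-bin
dispersion 0.02 (about 14% extra-Poisson noise per 10 kb bin, resembling
amplified single-cell libraries) is our choice, with dispersion 0 giving
Poisson. Coverage defaults follow the two study regimes, 0.15X (low-pass)
and 9.45X (deep). SNP depths follow the same mass model with binomial
alternate counts at the local paternal mass fraction; a region with zero
copies on both haplotypes yields zero depth. The replication-timing track
is a bounded, autocorrelated AR(1) process per chromosome, used both to
inject bias and as the correction covariate. Candidate SV tables contain
one junction per implanted cut plus artifact rows exercising each
downstream filter (low support, low mapping quality, strain background,
short intra-chromosomal distance), and `combine_sv_tables()` can add
recurrent cross-embryo artifacts — the class of false positives the
single-embryo rule removes. Synthetic EdU/DAPI images render nucleus and
micronucleus discs with per-structure DNA density and replication rate,
optional Gaussian noise, and exact ground-truth masks.

Simplifications worth noting: bins are statistically independent given
the karyotype (real amplification artifacts are spatially correlated and
would be absorbed by the cross-sample median); micronucleus state is
annotated on the harvested karyotype rather than re-segregated at each
division; chromatin-level processes (chromothripsis, rearrangement
graphs) are out of scope. Passing tests therefore demonstrate the
correctness of the inference rules under the stated noise model, not
robustness to every artifact of MDA-amplified libraries.

## Structural variants

SV discovery is external; the package consumes a BEDPE-like candidate
table and implements the downstream logic: drop candidates matching the
129S1/SvImJ strain background, supported by fewer than 3 reads in the
discovery sample, lacking a supporting pair with mapping quality above
30, or intra-chromosomal with breakpoints at most 1 Mb apart (distance is
undefined, and the filter vacuous, across chromosomes). The four filters
commute. Joint genotyping tallies split and discordant reads per sample
and marks presence at a configurable threshold (default 1 read — the
tallying step itself defines no cutoff, so the permissive default is
ours); SVs whose presence is confined to a single embryo are retained as
de novo candidates. The 3-read support filter is applied in the discovery
sample, as the per-sample discovery step implies.

## EdU quantification

Nuclei are segmented from the DAPI channel by Otsu thresholding, hole
filling and watershed splitting of touching objects (EBImage); the
largest object is the primary nucleus, remaining DAPI-positive objects
micronuclei, and a manual mask override replaces automatic segmentation
when provided. Per structure, EdU density is the background-subtracted
mean EdU divided by the background-subtracted mean DAPI, with the
background taken from a rectangular region near the nuclei — so a common
additive offset in both channels cancels exactly. Negative densities are
clamped to zero with a warning. The MN/PN ratio is reported only when the
primary nucleus is actively replicating, operationalized as
background-subtracted PN EdU of at least 10 arbitrary units on the
synthetic intensity scale (the gate is instrument-specific and exposed as
a parameter).

## Problem sizes and runtime

The default test fixture is a scaled toy genome (three telocentric
chromosomes of 120/80/50 Mb with a SNP every 10 kb; most tests use a
90 Mb three-chromosome variant with 20 kb native bins for speed). The
validation suite simulates 52 embryos across all six event classes plus
10 event-free embryos for the specificity check, runs the exhaustive
segmentation oracle on vectors of 8-12 bins, and completes in about two
minutes on one CPU. These sizes are the package's chosen desk-scale study
conditions; cohort-scale quantities (2.9M-SNP panels, hundreds of cells)
are represented by their scaled-down equivalents.

## Known limitations

* Whole-embryo events are only separable from locus bias with a reference
  cohort (see above); single-embryo runs of `run_pipeline()` will
  normalize a shared trisomy away unless a reference is supplied.
* The ploidy rule covers diploid and triploid genomes only, by design.
* Micronucleus events affecting half the blastomeres (division 1) distort
  the within-embryo locus median and can push the underreplicated
  haplotype off the half-integer grid; the events reported in this
  setting occurred at divisions 2-3, where the median is robust.
* Permutation p-values cannot call change-points on vectors shorter than
  about 15 bins at alpha = 0.01; use the default analytic route there.
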