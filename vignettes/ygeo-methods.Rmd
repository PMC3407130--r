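---
title: "Methods: Y-chromosomal structure and toponym-density regionalization"
author: "ygeo package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-chromosomal structure and toponym-density regionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In small alpine areas, settlement history leaves two independent traces:
place names, whose etymons (word roots) record which language groups
once farmed which valleys, and Y chromosomes, which are transmitted
patrilineally and — under the strong patrilocality typical of agrarian
mountain societies — stay geographically clustered for many centuries.
`ygeo` implements a complete analysis chain for testing whether a
present-day Y-chromosomal landscape still mirrors a regionalization
derived from toponym etymology: haplogroup calling from binary markers,
Y-STR haplotype statistics, population-distance and spatial-
autocorrelation inference, ordination, and density-based region
assignment, together with a forward simulator that generates data with
exactly the structure the analysis assumes, so that every stage can be
tested against known ground truth.

## Haplogroup calling on a binary marker tree

The Y-SNP panel is encoded as a rooted tree in which **every node is one
assayed marker position**.  A lineage's derived markers always form a
single root path, so a consistent fully typed profile is equivalent to
one node (its deepest derived marker) or to the all-ancestral ROOT
state.  Calls are labelled in the field's convention: major haplogroup
letter, hyphen, most derived marker, with a star (`R-S116*`) when the
terminal has typed children that are all ancestral — a *paragroup*.

Two markers of the shipped 27-marker panel are recurrent in the Y
phylogeny: SRY10831 (first mutated on the deep branch uniting
haplogroups B–T, back-mutated on the R1a branch) and P37 (haplogroup C
and I2a1).  The package represents recurrent markers as **one node per
phylogenetic position** (`SRY10831.1`/`SRY10831.2`, `P37.1`/`P37.2`).
This keeps the calling algorithm purely tree-based, and it is what makes
the panel's outcome space come out right: 29 marker positions yield
exactly 30 distinguishable haplo/paragroups (one per position, plus the
ROOT paragroup `Y*`).  Profiles that contradict a placement (derived
below a typed-ancestral parent, or derived on two branches) are rejected
with the conflicting marker pair named, rather than silently reassigned;
back-mutation inference is deliberately out of scope.

Missing markers on the path to a deeper derived marker are tolerated —
this mirrors the common typing strategy in which downstream markers are
only Sanger-typed for lineages where they are informative.  Without a
deeper confirmation the call truncates at the last confirmed derived
marker.

Paternal-relative deduplication groups records that agree on all three
of: haplogroup call, full 17-allele Y-STR profile, and a shared descent
indicator.  One member per group is kept, deterministically the
lexicographically smallest id, so repeated runs keep the same records.

Frequency tables report counts, relative frequencies, and modified-Wald
(add two successes and two failures) 95% confidence intervals,
\(\tilde p = (x+2)/(n+4)\), \(\tilde p \pm 1.96\sqrt{\tilde p(1-\tilde
p)/(n+4)}\) clamped to \([0,1]\).  Frequencies below the configurable
informativeness threshold (default 5%) are flagged non-informative.
Report percentages round half away from zero to one decimal.  Region
contrasts use Fisher's exact test (two-sided P by summing hypergeometric
probabilities at most that of the observed table, ties within a 1e-7
relative tolerance); multiplicity is handled by Benjamini–Yekutieli by
default — the false-discovery-rate variant recommended for correlated
tests in population genetics — with Benjamini–Hochberg and Bonferroni
(critical value \(\alpha/m\)) selectable.

## Y-STR preprocessing

The Yfiler panel carries two structural quirks the package normalizes
before any computation:

* **DYS389**: the DYS389II designation embeds DYS389I; all computations
  use the non-overlapping block DYS389b = DYS389II − DYS389I (a
  non-positive difference is a hard error).
* **DYS385**: a duplicated locus typed as an unordered allele pair.  It
  is removed from the default 15-locus numeric panel; in 17-locus mode
  the pair is compared as a 2-element multiset (each non-shared element
  is one difference; for multi-step counting the better of the two
  pairings is used).

Partial-repeat designations `x.y` at a locus with repeat unit length
`u` become `x + y/u` (so DYS458 17.2 is 17.5), `y >= u` is an error.  A
singleton locus showing two alleles (a locus duplication) is masked
missing.  Pairwise statistics are computed over the intersection of
non-missing loci without rescaling, and the intersection size is the
auditable quantity — this is the simplest contract and the one a reader
can recompute by hand.

Haplotype diversity is Nei's unbiased \(H = n(1-\sum p_i^2)/(n-1)\);
discrimination capacity is \(D = k/n\).  "Multi-step neighbor" counts
loci whose repeat difference is at least 2; the threshold is the natural
complement of the single-step mutation model and is exposed as an
argument.  Group dispersion contrasts use a label-permutation test on
the difference of group mean pairwise statistics (two-sided, `(b+1)/
(m+1)` convention); a two-sample t test on the pairwise values is
available for comparison but ignores the dependence among pairs sharing
an individual, so the permutation route is the default.

## Population distances

Pairwise \(\Phi_{ST}\) comes from a two-level analysis of molecular
variance on squared inter-haplotype distances (default metric: sum of
squared repeat-block differences; a count-of-different-loci metric is
provided for sensitivity analysis):

\[ SS_{tot} = \frac{1}{2N}\sum_{x,y} d^2_{xy}, \qquad
   SS_{w} = \sum_k \frac{1}{2n_k}\sum_{x,y \in k} d^2_{xy}, \]

with \(MS\) on \(K-1\) and \(N-K\) degrees of freedom,
\(n' = (N-\sum n_k^2/N)/(K-1)\),
\(\sigma^2_a = (MS_a - MS_w)/n'\) and
\(\Phi_{ST} = \sigma^2_a/(\sigma^2_a + MS_w)\).  P values shuffle
individuals between the pair of groups with the +1-corrected proportion
of permuted \(\Phi_{ST}\) at least the observed.  Negative estimates are
reported as computed (clamping is a display option), matching common
population-genetics practice.

Shannon mutual information \(^S\!H_{UA} = H_{pooled} - \sum_k (n_k/N)
H_k\) uses natural logarithms over whole-haplotype frequencies by
default; a per-locus-averaged mode is provided because some established
software computes per locus.  Both are reported by the pipeline and
compared only within a mode, since the two scales differ.

PCoA Gower-centers \(-\tfrac12 D^2\), eigendecomposes, and scales
eigenvectors by the square root of positive eigenvalues.  Distance
matrices such as \(\Phi_{ST}\) need not be Euclidean, so negative
eigenvalues are reported and excluded from variance fractions (which
are relative to the positive-eigenvalue total).

## Spatial autocorrelation

Genetic structure is tested against road distances, not straight-line
distances: in high-alpine terrain, ridges make Euclidean separation a
poor proxy for de facto separation, so the road-distance matrix is an
input (symmetrized with a 1e-3 km tolerance, and the triangle inequality
is deliberately not assumed).  Units (municipalities or individuals) are
paired into distance classes; the default is the "even pair counts"
scheme — pairs sorted by distance and split into k classes of near-equal
size, larger classes first, stable tie order — with **k = 6**, a package
choice: the source analyses used even sample sizes without printing the
class count, and six classes keep ≥60 pairs per class for a 29-unit
geography.

For the Gower-centered genetic matrix \(C\), the class-h coefficient is

\[ r(h) = \frac{\sum_{x \ne y,\,(x,y)\in h} c_{xy}}
               {\sum_x m_x(h)\, c_{xx}}, \]

with \(m_x(h)\) the number of class-h pairs involving x.  The null
shuffles units over locations (9,999 permutations by default); the 95%
envelope uses the \(\lfloor 0.025(m+1)\rfloor\)-th and
\(\lceil 0.975(m+1)\rceil\)-th order statistics of the permuted r, which
keeps two-sided exceedance at or below 5% exactly (interpolated
quantiles are anti-conservative at small m).  Bootstrap CIs resample
pairs within a class (9,999 by default).  The overall test uses
\(\omega = \sum_h r(h)^2\) against the joint permutation null with the
+1 correction; the replicate matrix is retained so the overall P can be
replayed and audited.

## Toponym density and regionalization

Per etymon class, the density surface counts points within a **closed**
10 km disc of each cell center, divided by \(\pi R^2\).  The closed-disc
rule is fixed so grid tests are bit-exact.  The default 1 km cell is a
package choice: well below the radius, so surfaces are stable, and cheap
to recompute.  Region assignment makes the published expert map-reading
rule explicit: a municipality is region A when Romance density exceeds
Slavic density at its location by at least a margin (default 0, strict
inequality), region B in the mirror case; ties fall back to an optional
fixed municipality table or are flagged unresolved.  Germanic-class
points never enter the assignment — they are dense everywhere in a
long-Germanized area and carry no contrast.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once:

* 29 municipalities in a ~55 × 40 km box, 270 retained probands split
  35 (region A, southwest) / 235 (region B), one dominant hub
  municipality (n = 99), plus 17 planted paternal-relative duplicates
  (287 raw records).
* Region-structured haplogroup founder frequencies anchored to the
  published regional pattern: the R1a clade (M17) at 0% in region A and
  16% in region B; R1b totals 68.6% vs 37.9%; I1/J/G2a at similar
  frequencies in both regions.
* Y-STR evolution under the symmetric single-step stepwise mutation
  model at μ = 2 × 10⁻³ per locus per generation (the upper end of
  typical Yfiler rates).  Generations since the haplogroup founders
  default to 120 — roughly three millennia at ~25 years per generation,
  the depth of the settlement processes at issue — which reproduces the
  observed scale of within-subclade dispersion (≈5–7 differing alleles
  per pair).  A star genealogy is used: each sampled lineage descends
  independently from its haplogroup founder.
* Patrilocal three-generation residence histories: per generation step
  the lineage moves municipality with probability 0.33 (90% of moves
  stay within region), father/grandfather municipalities are recorded
  with probabilities 0.759 and 0.687, matching the documented
  completeness of genealogical records.
* Road distances are Euclidean × 1.4, emulating valley networks
  without a road graph.
* 853 pasture-name points at 606/145/102 (71/17/12%) Germanic/Slavic/
  Romance; Slavic points cluster in the east and north, Romance in the
  southwest, Germanic uniform over the box.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: genealogical correlation within
haplogroups (a star genealogy has no shared internal branches, so
haplotype covariance within clades is understated), SNP genotyping
error (profiles are noiseless canonical states), locus-specific mutation
rates, real road topology, surname evolution, and reference populations
outside the study area.  Conclusions about those aspects need real
genotypes.

## Numerical conventions

* Permutation and bootstrap P values use the `(b+1)/(m+1)` correction
  everywhere; comparisons against observed statistics use a 1e-12
  absolute guard so exact ties count as "as extreme".
* Distance-matrix symmetry tolerance: 1e-3 km on input roads, 1e-8
  relative in matrix algebra.
* Even-pair-count classes break ties by stable pair order (row-major
  upper triangle); remainder pairs go to the earliest classes.
* Report rounding is half away from zero, one decimal, applied only in
  report columns, never in computations.
* All stage RNG is derived from one configured seed with fixed offsets;
  identical config and inputs give byte-identical outputs.

## Problem sizes in the shipped tests

The test suite exercises calibration properties at sizes chosen to make
the suite a routine desk run: permutation-uniformity and envelope
coverage use 200 replicates at 16–20 units with 99 permutations (the
+1-corrected P is exactly uniform at these sizes); the exhaustive Fisher
check enumerates every 2 × 2 table with total ≤ 40; parameter-recovery
checks run 100 full simulator replicates at the study's 35/235 split;
the stepwise-expectation check uses 1,000 independent lineage pairs
against an exact convolution oracle.  The pipeline's own defaults
(5,000 / 9,999 permutations) are used by `scripts/acceptance.R`.

## Known limitations

* The calling algorithm assumes the encoded tree is correct; it flags
  inconsistencies but performs no tree search or back-mutation rescue.
* \(^S\!H_{UA}\) permutation P values are not computed at the
  municipality-matrix stage (cost grows with the number of pairs times
  table constructions); the region-level contrast carries them.
* The density-based region rule is a two-class comparison; a genuinely
  trilingual contact zone would need a richer decision rule than
  A/B-with-fallback.
* Spatial autocorrelation at the individual level is supported by the
  same functions but scales as pairs × permutations; the pipeline runs
  it at municipality level, as the source analyses did.
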