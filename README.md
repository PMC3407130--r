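# ygeo

Tools for asking whether a present-day Y-chromosomal landscape still
mirrors settlement regions that were abandoned — linguistically —
centuries ago.

In alpine areas, pasture names preserve the word roots (etymons) of the
language groups that once farmed each valley, and density surfaces of
etymon-classified name points can partition a district into former
settlement regions. Y chromosomes, transmitted patrilineally and kept
geographically clustered by patrilocality, are the matching genetic
record. `ygeo` implements the full analysis chain connecting the two,
for population geneticists and interdisciplinary onomastics/genetics
studies:

* **Haplogroup calling** from binary Y-SNP profiles on a rooted marker
  tree, with the field's paragroup (star) naming. The packaged
  27-marker panel occupies 29 tree positions (the recurrent markers
  SRY10831 and P37 are encoded once per phylogenetic position) and
  distinguishes exactly 30 haplo/paragroups.
* **Y-STR haplotype statistics** for the 17-allele Yfiler panel:
  DYS389b derivation, DYS385 multiset handling, partial-repeat
  conversion, haplotype diversity *H*, discrimination capacity *D*,
  pairwise allele-difference and multi-step-neighbor dispersion with
  permutation contrasts.
* **Population structure**: pairwise AMOVA-based Φ<sub>ST</sub> with
  permutation P values, Shannon mutual information
  (<sup>S</sup>H<sub>UA</sub>), and principal coordinates analysis.

  Φ<sub>ST</sub> = σ²ₐ / (σ²ₐ + MS_w), with σ²ₐ = (MS_a − MS_w)/n′,
  n′ = (N − Σnₖ²/N)/(K − 1), from the sums of squares of inter-haplotype
  squared distances.
* **Spatial autocorrelation** (Smouse–Peakall) of genetic distance
  against road distance: per-class r with permutation envelopes,
  bootstrap CIs, and an overall ω = Σ r(h)² permutation test.
* **Toponym density regionalization**: circular-neighborhood (10 km)
  point-density grids per etymon class and explicit density-comparison
  assignment of municipalities to regions A/B.
* **A forward simulator** that generates the whole data world —
  stepwise-mutation Y-STR haplotypes descending from haplogroup
  founders, region-structured haplogroup frequencies, three-generation
  residence histories, planted paternal-relative duplicates, clustered
  pasture-name points — so every stage is testable against ground truth.

## Worked example

Simulate a study-scale dataset (29 municipalities, 287 raw samples,
853 pasture-name points) and run the pipeline end to end:

```r
library(ygeo)
print(ygeo_tree())
#> Y-SNP marker tree: 29 marker positions, 30 distinguishable haplo/paragroups

cfg   <- sim_config(seed = 1)
paths <- simulate_dataset(cfg, "demo")
res   <- run_pipeline(analysis_config(seed = 1), paths, "demo/out")

res$log[, 1:3]
#>                      stage n_in n_out
#> 1          read_population   NA   287
#> 2 dedup_paternal_relatives  287   270
#> 3         classify_regions   29    29
#> 4     generation_placement  270   270
#> 5         municipal_subset   29    29
```

287 raw records lose 17 paternal-relative duplicates (identical
haplogroup, identical 17-locus haplotype, shared descent group),
leaving 270 probands; all 29 municipalities are resolved to regions A/B
from the Romance-vs-Slavic density surfaces with zero misassignments
against the generator's truth.

```r
round(res$phist_region$estimate["A", "B"], 3)   # 0.109, P = 4e-04
round(res$shua_region$estimate["A", "B"], 3)    # 0.375
c(res$correlograms$phist$omega_p, res$correlograms$shua$omega_p)
#> 0.0382 0.0020
print(res$pcoa$phist)
#> PCoA: 29 points; 14 positive axes; first 3 axes carry 59.8%, 27.3%, 5.2%
subset(res$contrasts, haplogroup == "R-M17")[, c(1:3, 5, 7)]
#>    haplogroup count_a n_a count_b     p_value
#> 13      R-M17       0  35      36 0.006815067
```

Reading these numbers: the two toponym-derived regions differ
genetically (Φ<sub>ST</sub> = 0.109 between regions A and B, permutation
P = 4×10⁻⁴; mutual information 0.375 nats), the overall correlogram
tests reject spatial flatness (P = 0.038 for Φ<sub>ST</sub> distances,
0.002 for <sup>S</sup>H<sub>UA</sub>), the first principal coordinate
carries ~60% of the municipal Φ<sub>ST</sub> variance, and the planted
region-restricted clade (R-M17: 0/35 in region A, 36/235 in region B)
is flagged by Fisher's exact test (P = 0.0068). The pipeline writes
every table (frequencies with modified-Wald CIs, municipal Φ<sub>ST</sub>
and P matrices, correlograms, PCoA coordinates, density grids, region
map, stage log, JSON summary) under `demo/out/`.

A thin command-line wrapper with `simulate`, `run`, `call-haplogroups`,
`prep-haplotypes`, `diversity` and `distances` subcommands is installed
at `inst/cli/ygeo`.

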