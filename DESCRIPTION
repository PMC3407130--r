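Package: ygeo
Title: Y-Chromosomal Population Structure and Toponym-Density Regionalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking micro-geographic Y-chromosome population
    structure to settlement-history regionalization derived from place-name
    (toponym) etymology. Provides binary Y-SNP haplogroup calling on a
    rooted marker phylogeny with paragroup (star) naming, Yfiler Y-STR
    haplotype preprocessing (DYS389b derivation, DYS385 handling, repeat
    block conversion), haplotype diversity and pairwise dispersion
    statistics, AMOVA-based pairwise PhiST with permutation tests, Shannon
    mutual information between population and haplotype, principal
    coordinates analysis, Smouse-Peakall multivariate spatial
    autocorrelation against road distances with permutation envelopes and
    bootstrap confidence intervals, circular-neighborhood point-density
    surfaces for etymon-classified toponym points with density-based
    region assignment, and a seeded forward simulator (stepwise-mutation
    Y-STR haplotypes descending from haplogroup founders, region-structured
    haplogroup frequencies, three-generation residence histories, clustered
    toponym point clouds) that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
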