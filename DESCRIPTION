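Package: herdlink
Title: Cross-Country Pedigree Linkage and Population Structure for Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the genetic connectedness of livestock
    populations recorded in several national herdbooks: canonical animal
    identifier handling, pedigree validation and cross-country record
    linkage (exact, alias, suffix and fuzzy matching), connectedness
    tabulation, Meuwissen-Luo pedigree inbreeding, PED/MAP genotype
    quality control with variance-inflation-factor pruning, linkage
    disequilibrium decay and cross-population consistency of the gametic
    phase, VanRaden genomic relationships with principal component
    analysis, heterozygosity-based genomic inbreeding, and maximum
    likelihood admixture estimation with cross-validated choice of the
    number of ancestral clusters. A multi-country population simulator
    (Balding-Nichols divergence, mosaic founder haplotypes, gene
    dropping, identifier corruption) generates fully specified test data
    with known truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
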