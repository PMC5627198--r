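Package: igemap
Title: Mapping Direct and Indirect Genetic Effects in Recombinant Inbred
    Cross-Fostering Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) analysis of social (indirect)
    genetic effects in split-litter cross-fostering designs on recombinant
    inbred panels such as BXD.  Behavioural traits of genetically uniform
    individuals (B6 foster mothers and B6 half-litters) are mapped onto the
    genotypes of their genetically variable BXD litter mates, and direct
    effects are mapped in the BXD half-litters themselves.  Provides a
    GeneNetwork-style '.geno' reader/writer, covariate adjustment by
    backward-eliminated general linear models, Haley-Knott interval mapping
    with permutation genome-wide significance and 1.5-LOD support intervals,
    Benjamini-Hochberg selection across scans with Benjamini-Yekutieli
    protected follow-up tests, confidence-interval co-location of direct and
    indirect effects into named loci, and effect-size validation (peak-marker
    R-squared, allele direction, trait correlations, ANOVA broad-sense
    heritability).  A synthetic-data generator emulates the cross-fostered
    family design with known planted effects so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
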