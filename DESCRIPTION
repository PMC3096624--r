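Package: gmycdelim
Title: Species Delimitation on Ultrametric Gene Trees with the General
    Mixed Yule-Coalescent Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits the general mixed Yule-coalescent (GMYC) model to
    ultrametric gene trees to delimit putative species, with both
    single- and multiple-threshold variants, likelihood-ratio tests
    against a single-coalescent null, and profile-based confidence sets
    for the threshold. Includes the surrounding DNA-taxonomy workflow:
    haplotype/genotype collapsing under strict IUPAC symbol identity,
    alignment variation statistics (polymorphic and
    parsimony-informative sites), seeded one-individual-per-population
    subsampling, topotype-based naming of delimited entities,
    two-locus congruence assessment against a support-annotated tree,
    and simulators (Yule, coalescent, mixed Yule-coalescent trees and
    Jukes-Cantor alignments with diploid heterozygote emulation) so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
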