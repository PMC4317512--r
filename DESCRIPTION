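Package: breedsimr
Title: Stochastic Simulation of Marker-Assisted Breeding Strategies in Inbred Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-locus genetic simulation of inbred-line development in
    biparental wheat crosses. Simulates meiosis with recombination over a
    linkage map (Haldane map function), derives F2, recombinant inbred
    (bulk-selfed) and doubled-haploid progeny, and applies marker-assisted
    selection with F2 enrichment to compare three line-development
    strategies (F2-DH, RIL and modified single-seed descent) by the number
    of target genotypes recovered and by genetic gain per cycle and per
    year on an adjusted-fitness scale. Also predicts additive genotypic
    values for yield, height and ear emergence in multiple environments,
    and generates large simulated doubled-haploid populations under
    independence and pleiotropy scenarios. Ships the Avalon x Cadenza
    parental genotypes and target genotype as a packaged fixture together
    with a configurable synthetic-cross generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
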