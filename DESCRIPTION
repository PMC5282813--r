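Package: vfaferm
Title: Bioenergetics and COD Balance Analytics for Saline Mixed-Culture
    Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for carboxylate-platform (volatile fatty
    acid) fermentation of sugar-rich, saline substrates such as molasses.
    Evaluates standard and biologically corrected Gibbs energies of
    catabolic reactions (Gibbs-Helmholtz temperature compensation plus
    biological-standard-state pH correction), converts between mass, gas
    volume, biomass and chemical oxygen demand (COD) equivalents,
    computes acidification and methanogenesis yields with full COD
    mass-balance accounting for batch and continuously fed reactors,
    performs acid-base speciation and NaCl/conductivity salinity
    classification, and generates synthetic serial-batch enrichment and
    packed-bed reactor time series with exact COD closure for pipeline
    testing and pathway-weight recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
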