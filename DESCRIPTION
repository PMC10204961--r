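Package: ecfluxr
Title: Enzyme-Constrained Metabolic Models with Proteomics Integration and
    Flux Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific enzyme-constrained metabolic models
    from a stoichiometric network, a turnover-number (kcat) table, absolute
    proteomics and physiology measurements. Implements GECKO-style protein
    pool constraints, kcat matching with stepwise relaxation, biomass
    rescaling to measured protein and lipid content with a SLIME-style
    acyl-chain split, fitting of growth-associated maintenance energy,
    random sampling of the flux solution space with parsimonious weighted
    objectives, and derived summaries such as apparent catalytic activities,
    cofactor turnover and NADPH allocation trade-offs. Ships a synthetic-data
    generator emulating central carbon metabolism of an oleaginous yeast for
    ground-truth recovery testing, and a self-contained bounded-variable
    simplex solver for the underlying linear programs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
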