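Package: paleodelta
Title: Dynamic Delta Method Downscaling of Palaeoclimate Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage downscaling and bias correction of palaeoclimate
    simulation snapshots into high-resolution terrestrial climatologies.
    Stage one applies a Dynamic Delta Method in which fine-scale correction
    terms from a small set of high-resolution reference simulations are
    combined with weights derived from atmospheric CO2 similarity; stage two
    applies the classical additive Delta Method against a modern
    observational climatology. Includes Akima tensor-product regridding,
    inverse-distance gap filling over ocean cells, derivation of 17
    bioclimatic variables, annual temperature extremes, sea-level-driven
    land masks with ice-sheet overrides, proxy-based validation statistics,
    and a seeded synthetic-world generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'akima.R'
    'idw.R'
    'forcing.R'
    'delta.R'
    'extremes.R'
    'landmask.R'
    'bioclim.R'
    'validation.R'
    'synthetic.R'
    'io.R'
    'cli.R'
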