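Package: pepmarker
Title: Species-Specific Peptide Markers for Food Authentication by LC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for authenticating meat and plant ingredients in processed
    food from LC-MS peptide-mass data. Performs in silico tryptic digestion
    with missed cleavages and fixed/variable modifications, screens digestion
    products for species-unique (proteotypic) marker peptides against a
    taxon-tagged protein database, matches observed neutral monoisotopic
    masses to a marker panel at ppm tolerance, assembles replicate-consensus
    presence/absence detection matrices with protein-level rollups, calls
    species, identifies heat-stable markers across processing variants, and
    estimates protein-level limits of detection from spiked dilution series.
    Includes a seeded synthetic LC-MS feature generator (concentration-
    proportional intensities, log-normal noise, intensity-threshold dropout,
    Gaussian ppm mass error) and fixtures encoding a published hemp-in-
    meatball dilution experiment for end-to-end testing without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
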