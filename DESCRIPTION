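Package: glycanbabel
Title: Universal Glycan Nomenclature Conversion and Canonicalization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic detection, parsing and conversion of glycan sequence
    nomenclatures (WURCS 2.0, GlycoCT, LinearCode, GLYCAM, Oxford, KCF,
    IUPAC-extended, GlycoWorkbench, CSDB-linear and IUPAC-condensed dialects)
    into a single canonicalized IUPAC-condensed representation, with one
    unique string per molecule obtained by deterministic branch ordering on
    the glycan tree. Also parses and canonicalizes monosaccharide
    compositions (e.g. H5N4F1A2), repairs chemically impossible linkage
    assignments, and ships a seeded dialect-variant generator plus a
    cross-nomenclature fixture corpus used for round-trip testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
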