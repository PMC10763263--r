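Package: neoforge
Title: Structure-Guided Neoantigen Prioritization from Somatic Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates candidate mutant/wild-type peptide pairs from a
    somatic variant table (missense and frameshift), scores peptide/MHC
    class I fit with a pan-allele position-specific weight matrix trained
    on qualitative binding records and structural positives pooled across
    alleles with similar binding-pocket environments, applies consensus,
    RNA-expression and clonality filters, and classifies surviving
    candidates into four tiers separating MHC-anchor mutations from
    TCR-facing, physicochemically drastic mutations. Includes a synthetic
    data generator (planted weight matrices, binding records, variant
    cohorts, correlated external percentile-rank tables) so every stage is
    testable without external downloads, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
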