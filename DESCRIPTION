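Package: sirspread
Title: Single-Molecule Adenine-Methylation Footprinting of Heterochromatin Recruitment and Spread
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for single-molecule m6A footprinting of
    heterochromatin proteins in budding yeast. Per-read modified-base calls
    (Megalodon per-read text dialect) are binarized, aggregated into
    percent-methylated tracks, coverage-filtered and smoothed by
    coverage-weighted local regression; single-read methylation matrices,
    spread-boundary calls, nucleosome-linker periodicity, spread decay-length
    fits, differential methylation and silencing-establishment onset maps are
    derived from them. A parametric recruitment/spread/boundary occupancy
    model simulates per-read call sets with the statistical structure of the
    real assay so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
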