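Package: empaiq
Title: Label-Free Comparative Proteomics with emPAI Spectral Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiquantitative label-free protein quantification from
    spectral counts using the exponentially modified protein abundance
    index (emPAI). Provides in silico tryptic digestion and
    observable-peptide counting under an instrument scan window,
    per-strain mean-emPAI (MEP) and mean-square-deviation (MSD)
    summaries, interval-ratio differential-expression calls between two
    bacterial strains gated by a t-test, functional-category profiling
    with between-strain fold changes, theoretical pI/Mw distributions,
    delta-delta-Ct relative quantification of confirmatory RT-PCR data,
    and a synthetic-data generator that emulates a two-strain,
    six-runs-per-strain shotgun proteomics design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
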