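Package: tracedec
Title: Quantification of Targeted-Nuclease Indel Spectra by Sanger Trace Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spectrum and frequencies of insertions and deletions
    induced by a targeted nuclease (e.g. CRISPR/Cas9) in a pool of cells, from two
    capillary (Sanger) sequencing traces: a control and an edited sample. The
    composite trace downstream of the break site is modelled as a non-negative
    linear combination of the control trace shifted by every candidate indel, and
    the mixture is resolved by non-negative least squares, yielding per-indel
    frequencies with standard errors, p-values and an R-squared goodness of fit.
    Also infers the base composition of single-base insertions, reads ABIF (.ab1)
    and SCF v3 trace files as well as a plain-text fixture dialect, and ships a
    synthetic chromatogram generator so the whole pipeline can be exercised
    without sequencing hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    pracma,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
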