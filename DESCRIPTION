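Package: nmrcase
Title: Computer-Assisted Structure Elucidation from NMR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-assisted structure elucidation (CASE) engine. From a
    molecular formula and 1D/2D NMR peak tables (13C/1H peak lists, HSQC-type
    one-bond, HMBC-type long-range and COSY correlation tables) it builds a
    molecular connectivity diagram, exhaustively generates every candidate
    structure consistent with the correlation-derived distance constraints,
    predicts 13C chemical shifts by HOSE-code library lookup and ranks the
    candidates by mean absolute shift deviation. Also provides 13C-shift
    dereplication against structure and fragment libraries, molecular-formula
    and monoisotopic-mass searches, data-quality triage of peak tables, and a
    synthetic-spectrum simulator for round-trip validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
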