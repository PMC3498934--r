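Package: cellmatch
Title: Find Crystallographic Unit-Cell Matches in a Local Structure Database
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Identifies entries in a local macromolecular structure metadata
    database whose crystal lattices match a query unit cell. The query cell
    and every database cell are reduced to a canonical primitive (Niggli)
    P1 cell; cells are compared by least-squares superposition of the four
    cell vertex points over all six right-handed axis assignments, and hits
    within a distance cutoff are grouped into sequence families so that each
    distinct crystal form is reported once. Includes a database builder for
    mmCIF headers and tabular metadata dumps, a synthetic fixture generator
    with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
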