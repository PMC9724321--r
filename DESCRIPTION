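Package: ssfyield
Title: Mass-Balance Yields, Growth Rates and Cell Morphometry for
    High-Solids SSF Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for high-solids simultaneous saccharification
    and fermentation (SSF) experiments. Converts HPLC broth time courses into
    mass-balance-corrected glucose yields, glucan conversions and theoretical
    ethanol yields using anhydro correction factors and a sugar-dependent
    liquid-density correlation that accounts for the shrinking insoluble
    solids fraction; estimates exponential growth rates from OD600 series by
    log-linear window fitting; derives prolate-spheroid surface areas and
    volumes from measured cell axes; and simulates fermentation time courses,
    growth curves and cell-dimension samples with exact stoichiometric ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
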