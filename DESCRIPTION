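Package: stemflux
Title: Chamber-Based Greenhouse-Gas Flux Estimation, Upscaling and
    CO2-Equivalent Budgeting for Mangrove Stems and Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns static-chamber concentration time series (CO2, CH4, N2O)
    into quality-controlled areal fluxes via the ideal-gas linear-regression
    method, upscales them hierarchically from stem height intervals through
    per-tree, stem-area-weighted and forest-area-weighted annual fluxes, and
    converts the result into CO2-equivalent budgets with blue-carbon burial
    offsets and global first-order estimates. Includes a partial least
    squares structural equation modelling (PLS-SEM) estimator with the full
    reflective measurement and structural assessment workflow (reliability,
    AVE, HTMT, VIF, bootstrap inference, out-of-sample RMSE, BIC model
    selection), and a synthetic-data generator producing chamber campaigns
    and latent-variable datasets with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
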