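Package: iterlie
Title: Iterative Boltzmann-Weighted Linear Interaction Energy Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration and prediction toolkit for linear interaction
    energy (LIE) models of protein-ligand binding free energies that
    combine multiple molecular dynamics simulations per ligand (distinct
    protein conformations, docking poses and replicate runs) through
    self-consistent Boltzmann weighting.  Reads per-simulation average
    electrostatic and van der Waals ligand-surrounding interaction
    energies, converts IC50 inhibition data to experimental binding free
    energies, fits the LIE coefficients alpha and beta (or an alpha/gamma
    offset variant) by iterated weighted least squares, scans RMSE
    surfaces over the coefficients, and generates synthetic benchmark
    data sets with known ground-truth parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, tools, utils, yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
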