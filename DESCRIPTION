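Package: fretstab
Title: Analysis of FRET Binding Assays and Protein Stability Measurements
Version: 0.1.0
Authors@R:
    person("Plate", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of sensitized-emission FRET binding assays
    and protein-stability experiments. Converts three-channel plate-reader
    fluorescence into crosstalk-corrected sensitized emission and fits the
    quadratic ligand-depletion binding isotherm to obtain dissociation
    constants; fits four-parameter logistic inhibitor dose-response curves and
    converts IC50 to Ki via the Cheng-Prusoff relation; extracts melting
    temperatures and van't Hoff unfolding free energies from differential
    scanning fluorimetry melt curves; fits chemical-denaturation midpoints
    including biphasic (three-state) profiles; and estimates free-energy
    differences from nonequilibrium work distributions (Jarzynski,
    Crooks-Gaussian intersection, Bennett acceptance ratio) with
    thermodynamic-cycle closure checks. A synthetic-data module generates
    every input the pipeline consumes, with the statistical structure the
    analysis assumes, so all stages are testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
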