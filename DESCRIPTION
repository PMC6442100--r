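Package: cubiphase
Title: In Silico Formulation Screening and Analysis of Lipid Cubic-Phase Delivery Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mesoscale formulation screening for glyceryl-monooleate (GMO)
    lyotropic liquid-crystal drug carriers, together with the downstream
    experimental analytics used to characterize them. Provides a
    dissipative-particle-dynamics (DPD) engine parameterized from
    Flory-Huggins interaction parameters, microstructure classification of
    water-density fields (bicontinuous cubic, lamellar, intermediate,
    disordered), water-diffusivity and interfacial-tension observables, an
    optimization loop that selects the most fluid bicontinuous formulation,
    small-angle X-ray scattering (SAXS) peak indexing with lattice-constant
    fitting, Franz-cell permeation metrics (cumulative amount, steady-state
    flux, lag time, enhancement ratio), xenograft efficacy metrics (tumor
    volume, inhibition rate, group comparisons), and seeded synthetic-data
    generators with recorded ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
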