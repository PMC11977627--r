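Package: mapet
Title: Monolithic-Annulus PET Simulation, Reconstruction and NU4 Performance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained toolkit for a fourteen-facet monolithic LYSO
    annulus preclinical PET scanner. Provides a reduced-physics Monte Carlo
    simulator of annihilation-photon transport and scintillation light
    collection, the trigger/coincidence data-acquisition chain, light-map
    harmonization and neural-network event positioning, projection of lines
    of response onto virtual pseudo-detectors, single-slice-rebinned filtered
    backprojection and list-mode MLEM reconstruction, and a NEMA NU4-2008
    performance-analysis suite (spatial resolution, sensitivity, count rates
    and noise-equivalent count rate, image quality).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
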