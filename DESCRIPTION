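Package: gliosim
Title: Scenario-Based Reaction-Diffusion Simulation of Glioblastoma
    Growth on Labeled Brain Voxel Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of recurrent glioblastoma between
    successive MRI surveillance scans with a two-compartment
    (proliferating/quiescent) reaction-diffusion model on a
    patient-specific labeled brain voxel grid. Initial tumor cell
    densities are imputed from T1 post-contrast and T2/FLAIR image
    intensities inside expert segmentations, a fixed 18-scenario
    orthogonal-array parameter ensemble generates a range of plausible
    outcomes per imaging interval, and simulated density fields are
    re-segmented virtually to compare against the follow-up scan with
    volumetric and spatial overlap metrics. Includes a synthetic brain
    phantom generator so the whole pipeline can be exercised without
    patient data, plus a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
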