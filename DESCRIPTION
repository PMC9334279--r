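Package: tfusim
Title: Transcranial Focused Ultrasound Simulation and Tracer-Uptake Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for low-intensity pulsed transcranial
    focused ultrasound (tFUS) studies of cerebrospinal-fluid solute transport.
    Provides the algebra of pulsed-sonication parameters (duty cycle, pulse-average
    and temporal-average intensities, pressure-intensity conversions), a
    Rayleigh-Sommerfeld model of a single-element focused bowl transducer, mapping
    of CT Hounsfield units to voxelwise acoustic properties of skull bone, a
    finite-difference time-domain (FDTD) linear acoustic solver on heterogeneous
    media with intracranial reverberation, a Pennes bioheat solver for
    thermal-safety analysis under duty-cycled heating, acoustic-focus metrics
    (FWHM/FW90%M, local-maxima labeling, percent transmission), and image
    quantification pipelines for dye-infiltration scans and fluorescent
    CSF-tracer sections, together with seeded synthetic phantom generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    RNifti,
    EBImage,
    tiff,
    png,
    yaml,
    generics,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
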