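Package: lareims
Title: Simulation and Statistics for Laser-Assisted Rapid Evaporative
    Ionization Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing laser-assisted rapid
    evaporative ionization mass spectrometry (LA-REIMS) imaging
    experiments. One wing is a Monte Carlo simulator of the atmospheric
    interface: an underexpanded free-jet flow field with Mach-disk
    location, Knudsen-regime droplet transport with Cunningham slip
    correction, impact declustering on heated collision surfaces, a
    ring-electrode ion-guide capture model, and a geometry/temperature
    sweep optimizer. The other wing is the imaging statistics workflow:
    lock-mass recalibration, 0.1 Da spectral binning, total-ion-current
    normalization, raster image reconstruction, ion images and
    hyperspectral correlation maps, accurate-mass annotation, PCA-LDA
    tissue classification with leave-20%-out cross-validation and
    cross-modality transfer, and univariate volcano analysis. Synthetic
    phantom and aerosol generators provide ground-truthed inputs for
    both wings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
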