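Package: sensimorph
Title: Morphometrics of Female Damselfly Thoracic Sensilla
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mechanosensory sensilla phenotypes on the
    mesostigmal plates of female damselflies from digitized microscope
    coordinates. Reads plate-outline and sensilla coordinate files, computes
    per-female scalar traits (sensilla count, plate area, sensilla-region hull
    area, coverage proportion, density, nearest-neighbor distances), pools
    size-standardized sensilla clouds within populations and compares their
    spatial distributions with a two-sample kernel density permutation test
    (integrated squared error statistic, Benjamini-Hochberg correction across
    population pairs), computes population mean plate shapes by generalized
    Procrustes analysis of resampled outline semilandmarks, and runs the
    sympatry-versus-allopatry statistical battery (Welch t, Kruskal-Wallis,
    Bartlett, linear regressions) on population means. A synthetic-study
    generator emulates two species differing in sensilla number and
    medial-versus-lateral placement, with technical digitization replicates,
    so the whole pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
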