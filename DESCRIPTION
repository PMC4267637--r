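Package: wormtrace
Title: Worm-Like Chain Statistics and Contour Tracing for AFM Images of DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether short DNA bends smoothly or kinks,
    from atomic-force-microscopy (AFM) style data. Simulates planar discrete
    worm-like chains at base-pair resolution from harmonic and kinkable
    (linear sub-elastic chain) bending potentials, renders chains into
    synthetic AFM height images with tip-broadened ridges and helical
    centerline undulation, traces filament contours by an iterative
    prediction-correction scheme with sub-pixel centerline refinement,
    models the irreducible localization noise of the double-helix width as
    bisector shifts, and estimates bending persistence length from
    bend-angle distributions with chord-discretization corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
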