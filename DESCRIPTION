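Package: cmzclone
Title: Clonal Dynamics and Division Geometry of the Ciliary Marginal Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic branching-process simulation of retinal progenitor
    clones in the continuously growing fish retina, with embryonic and
    ciliary-marginal-zone (CMZ) variants; a stem-cell niche division model
    with tunable division asymmetry; clonal statistics (clone
    classification, niche detachment rates, peripheral-ring distributions,
    fate-pair matrices and clone-composition tests); annulus geometry for
    ring assignment and oriented-division angles; and a frame-difference
    division detector for 4D time-lapse movies, validated on synthetic
    movies with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tiff,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
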