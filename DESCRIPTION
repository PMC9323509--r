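Package: cellsolute
Title: Cell-Solute Reaction-Diffusion Modelling of Stabilised Collagen Gel Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-domain (gel + culture medium) one-dimensional finite-volume
    model of oxygen, glucose and VEGF transport coupled to viable-cell density
    in plastic-compressed, cell-seeded collagen gels cultured in multiwell
    plates under controlled ambient oxygen. Oxygen and glucose are consumed by
    Michaelis-Menten kinetics (with an anaerobic enhancement of glycolysis),
    VEGF secretion is hypoxia-gated and crowding-limited, and cell death
    increases under nutrient deprivation. The package also provides Morris
    elementary-effects screening of the 19 model constants, a two-step
    particle-swarm calibration against the four experimental observation
    blocks (centre-gel oxygen traces, 24-h medium glucose, gel viability and
    medium VEGF), and a synthetic pseudo-experiment generator for recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
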