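Package: owlshift
Title: Climate-Envelope Forecasting of Montane Owl Breeding Habitat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to forecast climate-driven shifts in vegetation-based
    breeding habitat for owls of semi-arid montane landscapes. Implements
    climate-envelope vulnerability scoring of mapped vegetation types
    (Ecological Response Units), rule-based projection of late 21st-century
    vegetation, rendering of species habitat profiles to raster habitat
    maps, habitat extent and patch change metrics, territory transition
    summaries, and the validation statistics used with such models
    (spatially constrained randomization nulls with one-tailed z-tests,
    and McNemar paired change tests). A seeded synthetic-landscape
    generator emulates the elevational zonation of vegetation and its
    climate structure so the full pipeline is testable without geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
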