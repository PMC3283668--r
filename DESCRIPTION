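Package: firecoex
Title: Fire-Driven Coexistence of Grass Functional Types on a Lattice
Version: 0.1.0
Authors@R:
    person("firecoex", "maintainers", email = "firecoex@example.org",
           role = c("aut", "cre"))
Description: Spatio-temporal simulation of three competing grass functional
    types (an obligate seeder, an obligate resprouter and a facultative
    resprouter) on a lattice of patches. Each patch holds stage-structured
    populations projected with Lefkovitch matrices and modified by three
    stochastic spatial processes: probabilistic fire with a one-generation
    fuel (refractory) memory and a variable spatial scale, mode-specific
    dispersal (neighbour-limited vegetative spread versus mostly-local,
    occasionally-global seed rain), and a multinomial survival lottery that
    enforces the patch carrying capacity. Includes closed-form oracles for
    the fire process (stationary burnt fraction and time-since-fire
    distribution), a regime-grid sweep over fire probability and fire
    scale in single-species, pairwise and full-community configurations,
    and Shannon-Wiener diversity surfaces used to locate the fire regime
    that permits three-way coexistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
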