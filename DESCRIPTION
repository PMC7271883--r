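Package: canopyforage
Title: Habitat-Domain Overlap, Foraging Energetics and Movement Models for
    Canopy Arthropod Predators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing vertical habitat domains of canopy
    arthropods and the consequences for predator-prey interactions.
    Fits normal and gamma vertical-density models to behavioural
    observations, computes overlap-based encounter and attack rates,
    evaluates a temperature-dependent net-energy-gain model for a
    sit-and-wait spider hunting at different canopy heights, optimises
    attack strategies by combining signal detection theory with
    habitat-domain encounter composition, simulates perch movement with
    an individual-based model, and fits hierarchical Bayesian models of
    treatment effects on height and of grasshopper survival.  A
    synthetic-data generator emulates the cage-experiment design so the
    whole pipeline can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
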