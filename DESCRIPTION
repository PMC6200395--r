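Package: pumpleak
Title: Pump-Leak Models of Neuronal Chloride and Volume Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical pump-leak modelling of neuronal chloride homeostasis.
    Implements a single-compartment cell with charge-difference membrane
    potential, a sodium-dependent cubic Na+/K+-ATPase, KCC2 cation-chloride
    cotransport, impermeant anions of arbitrary mean charge, and explicit
    osmotic (or tension-constrained) water flux; a damped-Newton steady-state
    solver with parameter sweeps; a protocol engine for timed manipulations
    (pump ramps, impermeant-anion injection, mean-charge ramps, bath swaps);
    and a multi-compartment 'virtual dendrite' coupled by Nernst-Planck
    electrodiffusion. Forward-Euler integrators are compiled for speed.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
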