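Package: dnapairpmf
Title: Effective Pair Potentials Between Linear and Circular DNA from
    Coarse-Grained Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for computing the effective pair potential
    V_eff(r) between two short DNA molecules (a 24-bp linear duplex or a 65-bp
    torsionally relaxed minicircle) in monovalent or divalent electrolyte.
    Builds one-bead-per-basepair charged models with explicit counterions and
    co-ions in a periodic box, samples umbrella-biased configurations along the
    centre-of-mass separation with Metropolis Monte Carlo, reconstructs the
    unbiased potential of mean force with the weighted histogram analysis
    method (WHAM), and provides the conformational and ion-atmosphere
    observables that rationalise topology- and valence-dependent repulsion:
    gyration-tensor principal axes and pair orientation angles, 2D Gaussian
    kernel density estimates, superposition-based RMSF profiles, ion-site
    radial distribution functions and first-shell coordination numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
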