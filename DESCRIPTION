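Package: capsim
Title: Event-Driven Simulation of Phase Ternary Computation with
    Computational Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates neural computation by collision of computational
    action potentials (CAPs), modelled as ternary phase quanta: an
    activation-threshold instant followed by an absolute refractory
    window.  CAPs propagate along neurites at fixed conduction velocity
    and interact at convergence nodes, where overlapping thresholds
    fuse, a threshold falling inside another CAP's refractory window is
    annulled, and a threshold arriving after the window passes.  The
    package provides an event-driven network engine with a brute-force
    dense-time lattice oracle for verification, a retinal convergence
    model (grouped receptors onto a bipolar cell and retinal ganglion
    cell) computing refractory-gated mean sampling, the associated
    precision and ternary information calculus, phase-length accounting
    on network edges, seeded generators for periodic and dead-time
    censored Poisson threshold trains, a spike-peak jitter model
    contrasting threshold-timed with peak-timed codes, and plain-text
    readers and writers for networks and trains with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
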