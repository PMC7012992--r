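Package: pspmreduce
Title: Exact ODE Reduction of Physiologically Structured Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decides whether a physiologically structured population model
    (PSPM) with deterministic individual-state dynamics admits an exact
    finite-dimensional ODE representation, and constructs that representation.
    Model ingredients (growth rate, death rate, Dirac-mixture birth law and
    output weight functions) are handled symbolically in separated form
    (environment monomials times i-state functions); the backward operator is
    applied exactly and the invariant weight-function space is grown by
    iterated span closure until it closes, yielding the weight basis and the
    matrices K(E), H(E), M(E) and Q(E) of the reduced system dN/dt = K(E)N.
    Includes constructors and identity checks for the complete catalogue of
    reducible one-dimensional model families (scalar survival weights,
    physiological-age models with matrix-exponential weights, generalised von
    Bertalanffy growth), the age-structured linear chain trick with density
    recovery, Kac-Sylvester and trigonometric matrix identities, and a cohort
    (characteristics) simulator that cross-validates reductions against
    direct simulation of the structured model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
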