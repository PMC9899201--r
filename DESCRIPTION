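Package: tickdde
Title: Tick Attachment and Host Grooming Dynamics via Algebraic-Delay
    Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the tick-host interface as a coupled system of a delay
    differential equation for engorged nymphal ticks and an algebraic
    (integral) equation for feeding nymphal ticks, where tick attachment and
    host grooming rates depend on the feeding-tick load. Provides equilibrium
    solvers for constant, monotone, Ricker (cooperative feeding) and
    Holling type III (grooming reactive to biting) behaviour families,
    stability classification via small-feeding-duration perturbation
    expansions of the characteristic equation, and a method-of-steps
    integrator for the full delay system with matching-condition history
    construction and algebraic-constraint monitoring. Built-in presets
    reproduce bi-stable and quadri-stable equilibrium configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
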