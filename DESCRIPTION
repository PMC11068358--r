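Package: dynres
Title: Dynamic Neural Resource Modelling of Visual Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and maximum-likelihood fitting of a dynamic neural
    resource model of visual sensory and working memory. Continuous-report
    errors in orientation recall are modelled as maximum-likelihood decoding
    of Poisson spiking in an idealized tuned population, whose gain follows
    low-pass sensory filtering and normalization-limited accumulation into
    working memory, with diffusion of stored values and swap (misbinding)
    errors. Includes a trial-level forward simulator for standard delayed
    estimation designs, predicted error densities, multi-start Nelder-Mead
    fitting of the full model and a family of reduced variants, AIC model
    comparison, and parameter-recovery tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
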