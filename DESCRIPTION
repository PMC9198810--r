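Package: sewir
Title: Stability and Intervention Analysis for an SEWIR Epidemic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a five-compartment SEWIR epidemic model in which the
    exposed class is split into unquarantined (E) and medically quarantined (W)
    subclasses, with continuous vaccination of susceptibles (success rate m)
    and a government control rate (k1) moving exposed individuals into
    quarantine. Provides the basic reproduction number in closed form and via
    the next-generation matrix, disease-free and endemic equilibria,
    local-stability classification through Routh-Hurwitz minors and Jacobian
    eigenvalues, a Lyapunov diagnostic for global stability of the
    disease-free state, deterministic ODE simulation with piecewise-constant
    intervention schedules, trajectory summaries (peaks, threshold crossings),
    scenario bundles, and R0 sensitivity surfaces over (m, k1). Results are
    returned as tibbles with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
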