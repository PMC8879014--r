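Package: hnpso
Title: Hybrid Neural-Network Particle-Swarm Models for Heavy Metals in Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts heavy-metal concentrations (Cr, Cd, Fe, Mn, Zn, Ni, Pb,
    Cu) in surface water and groundwater from four in-situ physicochemical
    parameters (temperature, pH, electrical conductivity, total dissolved
    solids). A single-hidden-layer tansig network is trained by particle
    swarm optimization of its full weight/bias vector, with optional damped
    Gauss-Newton refinement, early stopping on validation error, and
    topology selection over 1-30 hidden neurons at the Akaike information
    criterion minimum. Includes Kling-Gupta efficiency scoring, linear and
    kernel regression baselines, Olden connection-weight sensitivity
    analysis, and a copula-based synthetic data generator calibrated to
    published descriptive statistics of acid-mine-drainage-impacted waters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    e1071,
    jsonlite,
    withr
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
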