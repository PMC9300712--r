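Package: biosorb
Title: Response-Surface, Neural-Network and Genetic-Algorithm Modelling of
    Heavy-Metal Biosorption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling and optimising biosorption processes, built
    around a worked arsenic(III) removal study on an iron-impregnated fungal
    biofilter. Provides a central composite design (CCD) data model with
    coded/actual factor transforms and a packaged 31-run example dataset;
    ordinary least-squares fitting of the full quadratic response surface with
    ANOVA (including lack-of-fit against centre replicates) and box-constrained
    surface maximisation; a small feed-forward neural-network surrogate (4-H-1)
    trained by batch gradient descent with momentum and an adaptive learning
    rate; a real-coded genetic algorithm (roulette selection, single-point
    crossover, Gaussian mutation, elitism) for maximising a surrogate over
    factor bounds; batch sorption analysis (Langmuir and Freundlich isotherms,
    pseudo-first and pseudo-second order kinetics, Van't Hoff thermodynamics);
    fixed-bed breakthrough-curve metrics (breakthrough and exhaustion times,
    treated volumes, uptake, empty-bed contact time, sorbent usage rate, BDST
    critical bed height); and seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
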