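Package: abilitygame
Title: Evolution of Ability in a Two-Player Public Goods Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the evolution of a heritable ability trait
    when individuals interact pairwise over a common good and efforts are in
    Nash equilibrium. High ability lowers the marginal cost of effort, but a
    partner's compensating response can make low ability pay. The package
    computes Nash-equilibrium efforts for ability pairs, invasion fitness and
    selection gradients, pairwise invasibility plots, and singular-point
    classification (convergence stability, evolutionary stability, branching
    points), and runs agent-based evolutionary simulations under sexual
    (infinitesimal-model) and asexual inheritance, including a bimodality
    statistic for detecting evolutionary branching. A command-line interface
    exposes the analyses and figure-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
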