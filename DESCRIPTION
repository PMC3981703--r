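Package: polymate
Title: Embodied Evolution of Polymorphic Mating Strategies in Robot Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of a small colony of hermaphrodite
    foraging robots that reproduce by physical genotype exchange, with no
    explicit fitness function or centralized selection.  Each individual
    carries a 51-gene real-valued genotype encoding a linear mating-strategy
    network, potential-based shaping rewards, and reinforcement-learning
    meta-parameters; the basic behaviors (foraging, waiting, mating) are
    learned within each lifetime by Sarsa with tile coding.  The package
    provides the arena simulation, the embodied genetic algorithm, waiting
    threshold phenotyping and forager/tracker classification, fixed-proportion
    mixture experiments, a mating-mix fitness model, and discrete replicator
    dynamics with attractor detection on the phenotype simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
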