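Package: pignpi
Title: Physics-Induced Graph Networks for Learning Pairwise Particle Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns pairwise forces or pairwise potential energies from observed
    particle trajectories using a graph network whose node update is a fixed
    Newtonian physics operator rather than a learned function. An edge
    multilayer perceptron is trained only on particle accelerations; Newton's
    second law (and, in potential mode, the force-as-negative-gradient
    relation) is imposed deterministically in the node part, so the learned
    edge messages recover physically consistent pairwise interactions.
    Includes trajectory simulators for benchmark pair laws (spring, charge,
    orbital, discontinuous) and Lennard-Jones argon with periodic boundaries,
    purely learned graph-network baselines, symmetry-regularized and
    learnable-scale variants, finite-difference kinematics, noise injection,
    and physics-consistency metrics for inferred forces and potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
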