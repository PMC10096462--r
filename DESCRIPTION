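Package: spinlabelr
Title: In Silico Spin Labeling of Protein Structures
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Attaches weighted rotamer ensembles of paramagnetic spin labels
    to protein structures, scores them against the local environment with a
    flat-top repulsive Lennard-Jones potential, and derives experimental
    observables for site-directed spin labeling EPR: inter-label distance
    distributions (DEER), spin centroids, and membrane immersion depths.
    Includes site-pair screening by earth-mover's distance, creation of
    portable rotamer-library archives from multistate conformer PDB files,
    Markov-chain Monte Carlo side-chain repacking, and rigid-body membrane
    docking from depth restraints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
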