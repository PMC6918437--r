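Package: hpfmd
Title: Hybrid Particle-Field Molecular Dynamics for Block-Copolymer Micellization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single-node reference implementation of hybrid particle-field
    molecular dynamics (MD-SCF) for coarse-grained amphiphilic block copolymers
    in mixed solvents. Non-bonded interactions are replaced by mean-field
    external potentials derived from per-species density fields on a periodic
    mesh; bonded interactions are harmonic springs integrated with velocity
    Verlet under an Andersen thermostat. Includes Flory-Huggins
    parameterization from Hildebrand solubility parameters, a system builder
    for volume-fraction recipes, and micelle characterization (aggregation
    numbers, gyration-tensor shape descriptors, radial density profiles, mean
    squared displacement), with extended-XYZ trajectory I/O and a small
    command-line surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, igraph, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
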