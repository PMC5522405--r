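Package: tgtunnel
Title: Triglyceride Conformation and Protein Descriptors for Lipid-Transfer Tunnel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory descriptors for neutral lipids bound in the hydrophobic
    tunnel of lipid-transfer proteins such as CETP. Builds per-chain sn1/sn2/sn3
    vectors on triglycerides from atomistic or coarse-grained frames, classifies
    single-lipid and lipid-pair orientation states (head-to-legs, legs-to-head,
    parallel/antiparallel pair taxonomy), computes whole-protein bending and
    twisting angles from domain centres of mass, Kabsch superposition RMSD and
    trajectory-average structures, and counts protein-lipid contacts under a
    distance cutoff with residue-level gained/lost/common comparisons. Includes
    a seeded synthetic-trajectory generator with known per-frame ground truth
    for end-to-end validation, and readers/writers for PDB, GRO and a plain
    per-frame CSV trajectory dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
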