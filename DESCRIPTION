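Package: flytrap
Title: Opening and Closure Event Detection in Two-Domain Hinge Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Flytrap", "Maintainers", email = "maintainers@flytrap.example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis for periplasmic binding proteins (PBPs) and other
    two-domain hinge proteins that interconvert between an open and a closed
    conformation ("Venus flytrap" mechanism). Provides multi-model PDB input/output,
    heavy-atom and C-alpha Kabsch superposition, inter-domain distance/angle/dihedral
    metrics, radius of gyration, Shrake-Rupley solvent-accessible surface area,
    omega-angle cis/trans proline classification, Gaussian native-contact scores
    Q(NC) and q(similarity) against open/closed references, endpoint-window box
    summaries, crossover-based conformational-event detection with multi-metric
    concurrency scoring, and a seeded synthetic hinge-trajectory generator with
    ground-truth events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
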