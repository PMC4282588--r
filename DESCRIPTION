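Package: specflex
Title: Specificity-Flexibility Profiling of Protease Subpockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies protease substrate specificity from cleavage-site
    tables via per-subpocket cleavage entropy, profiles binding-site
    flexibility from molecular-dynamics trajectories (per-residue C-alpha
    B-factors, hydrogen-bond occupancies, distance statistics, with dimer
    averaging), and correlates the two by Spearman rank correlation.
    Includes synthetic-data generators (substrate sets with prescribed
    positional distributions, toy dimeric trajectories with Gaussian
    fluctuations, hydrogen-bond and distance series with known ground
    truth) so the whole pipeline is testable without running simulations,
    plus Kabsch superposition with iterative outlier rejection and
    multi-model PDB input/output for flexibility landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
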