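Package: prscan
Title: Perturbation Response Scanning with Cutoff-Free Elastic Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies allosterically responsive residues in protein
    structures by perturbation response scanning (PRS): a coarse-grained
    C-alpha elastic network whose spring constants decay with the inverse
    square of the inter-residue distance (no interaction cutoff) is coupled
    with linear response theory to compute residue displacement responses
    to directed unit forces.  Forces applied on binding-pocket residues
    yield a per-residue allosteric response ratio (chi); residues whose
    dominant response directions align are chained into maximum-weight
    intramolecular signalling pathways; response vectors also drive the
    generation of perturbation-displaced conformational ensembles for
    flexible docking.  Includes contingency-table evaluation against
    reference residue sets (Fisher's exact test) and Kabsch RMSD
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    MASS,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
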