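Package: ppiface
Title: Region-Resolved Analysis of Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein-protein interface residues into core, support,
    rim and rim non-interacting-surface regions from changes in relative
    solvent accessibility upon binding, detects a broad catalogue of
    non-bonded residue-residue interactions (hydrogen bonds, salt bridges,
    pi systems, chalcogen bonds, packing contacts, clashes and repulsions)
    by explicit geometric criteria, and computes region-resolved statistics:
    buried surface area accounting, physicochemical composition and
    partitioning, residue stickiness, mean interaction count per capable
    pair, Shannon entropy and evenness of interacting pair classes, tf-idf
    filtering and pointwise mutual information of pair-class co-occurrence,
    and binding-affinity-based classification of complexes into stable,
    intermediate and transient. Includes a synthetic-structure generator
    producing analytic solvent-accessibility toys, burial-controlled dimers
    and ideal interaction geometries so the full pipeline is testable
    without downloading any structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
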