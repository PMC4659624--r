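Package: helixswitch
Title: Geometric and Interfacial Analysis of G-Protein alpha5 Helix-Switch Motions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the screw-like repositioning ("helix-switch") of
    the G-protein alpha5 C-terminal helix within the cytoplasmic crevice of an
    activated G-protein-coupled receptor. Provides multi-model PDB input/output
    with an atom selection language and anchor-propagated Ballesteros-Weinstein
    generic numbering; Kabsch superposition, helix-axis fitting, and screw
    (Chasles) decomposition of rigid motions; single-linkage clustering and
    contact-register classification of peptide binding poses; interface
    characterization (hydrogen bonds, cation-pi contacts, Shrake-Rupley buried
    surface area, bridging waters); per-frame trajectory metrics with running
    averages and switch-event detection; and seeded synthetic-data generators
    (ideal helices, planted screw motions, clustered pose sets, interface
    scenes) so every analysis can be exercised without external coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
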