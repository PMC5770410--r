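Package: pepfab
Title: Fragment-Based Peptide Models for 3D Printing and In Silico Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds hybrid physical/computational peptide models for
    structure-based drug design. Segments a peptide chain into rigid
    fragments hinged at rotatable torsion angles (phi, psi, chi), emits
    parametric constructive-solid-geometry scripts (OpenSCAD dialect) for
    3D-printable fragments, receptors, molded templates, measurement ticks
    and charge glyphs, and evaluates reported conformations in silico:
    torsion-driven coordinate reconstruction, Lennard-Jones plus Coulomb
    nonbonded energies, hard-sphere feasibility at scaled van der Waals
    radii, Ramachandran-style two-torsion grid scans, and discrete
    dot-surface contact scoring against a molded receptor template.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
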