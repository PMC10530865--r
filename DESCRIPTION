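Package: seedgrow
Title: Fragment-Seeded Growing of Peptide Ligands in Protein Binding Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs atomic-resolution protein-peptide complex structures
    by docking a capped dipeptide fragment ("seed") of the peptide into the
    target's binding region, growing the full peptide in situ from each
    ranked seed pose with Ramachandran-basin backbone sampling and rotamer
    side chains, scoring the resulting model pool with a pairwise
    intermolecular 12-6 Lennard-Jones plus Coulomb energy under the
    Mehler-Solmajer distance-dependent dielectric, and selecting the model
    closest to the mean coordinates of the top-scoring fraction. Includes
    heavy-atom RMSD evaluation against reference complexes and a synthetic
    planted-complex fixture generator, motivated by histone-tail/reader
    systems where mostly the first few N-terminal residues anchor the
    peptide.
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
    jsonlite,
    withr
Config/testthat/edition: 3
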