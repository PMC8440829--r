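Package: gnmflux
Title: Ligand-Perturbation Analysis of Protein Fluctuations with the
    Gaussian Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-residue fluctuation profiles for ligand-bound and
    ligand-free forms of a protein structure using the Gaussian network
    model (GNM), a coarse-grained elastic network built on C-alpha atoms
    and ligand heavy atoms connected by identical springs within a distance
    cutoff.  Provides the bound-minus-unbound fluctuation difference
    profile, an increase/decrease ratio statistic with conditional means, a
    seeded single-atom decoy-ligand control, a radial profile of
    fluctuation change versus distance from the ligand, structure
    preparation utilities (PDB input/output, ligand stripping, Kabsch
    superposition, ligand transplantation, B-factor painting), and
    synthetic-structure generators with closed-form reference models for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    MASS,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
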