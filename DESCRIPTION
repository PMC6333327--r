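Package: nonaffine
Title: Non-Affine Displacement Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes local atomic displacements in protein conformational
    ensembles into affine and non-affine subspaces by least-squares
    projection, and computes the per-atom non-affine parameter (NAP), its
    ensemble susceptibility, the eigen-spectrum of the projected displacement
    correlator with its spectral gap, dominant non-affine modes, and
    residue-residue NAP covariance maps. High NAP susceptibility flags
    candidate ligand hotspots on apo proteins; large NAP covariance between
    spatially distant residues flags candidate allosteric pairs. Includes a
    synthetic-ensemble generator (affine schedules, isotropic noise, planted
    soft modes, graded-softness clusters, conjugate-field Gaussians) so every
    claim is testable without external data, plus Marchenko-Pastur
    random-matrix comparison of the spectrum.
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
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
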