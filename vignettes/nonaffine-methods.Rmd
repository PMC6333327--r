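---
title: "Non-affine displacement analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-affine displacement analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonaffine)
```

## The model

Thermal motion of a folded protein, observed against a fixed reference
structure $\{\mathbf{R}_i\}$, decomposes locally into two orthogonal
parts. Within a neighborhood $\Omega_i$ of atom $i$, a displacement field
is *affine* if the relative displacements of all members are generated by
one linear map, $\boldsymbol{\Delta}_{ij} = \mathsf{D}(\mathbf{R}_j -
\mathbf{R}_i)$ for some $3\times 3$ matrix $\mathsf{D}$ — this covers
rotations, strains and shears of the local environment. Everything else
is *non-affine*, and it is the non-affine component that carries
conformational rearrangement: gate openings, hinge motions, cavity
breathing.

The non-affine parameter of site $i$ in one frame is the irreducible
least-squares error of the affine model,

$$\chi_i \;=\; \min_{\mathsf{D}} \sum_{j \in \Omega_i}
  \left\| \boldsymbol{\Delta}_{ij} - \mathsf{D}\,(\mathbf{R}_j -
  \mathbf{R}_i) \right\|^2
  \;=\; \boldsymbol{\Delta}^{\mathsf T} \mathsf{P}\, \boldsymbol{\Delta},
  \qquad
  \mathsf{P} = \mathsf{I} - \mathsf{R}(\mathsf{R}^{\mathsf T}
  \mathsf{R})^{-1} \mathsf{R}^{\mathsf T},$$

where $\boldsymbol{\Delta}$ stacks the member displacements
($x,y,z$ contiguous per member, members in ascending atom order) and
$\mathsf{R}$ is the $(n_\Omega d) \times d^2$ geometry matrix
$\mathsf{R}_{j\alpha,\gamma\gamma'} = \delta_{\alpha\gamma}(\mathbf{R}_j -
\mathbf{R}_i)_{\gamma'}$. The equivalence of minimisation and projection
is an exact linear-algebra identity; the package implements both routes
(`chi_direct` via the normal equations, `chi_projected` via the cached
projector) and the test suite holds them to $10^{-8}$ relative agreement
on randomized instances. One convention matters: we fit $\mathsf{D}$ to
the *relative displacements* $\boldsymbol{\Delta}_{ij}$, so for a frame
produced by the position map $\mathbf{r} = \mathsf{A}\mathbf{R}$ the
fitted matrix is $\mathsf{A} - \mathsf{I}$. A formulation that fits
positions directly differs only by that identity shift; $\chi$ is
identical in both.

Ensemble statistics follow from the local displacement correlator
$\mathsf{C} = \langle \boldsymbol{\Delta}\boldsymbol{\Delta}^{\mathsf T}
\rangle$:

- $\langle\chi\rangle = \sum_\mu \lambda_\mu$ where $\lambda_\mu$ are the
  eigenvalues of $\mathsf{P C P}$ (the trace identity; exact because we
  do **not** subtract the mean displacement from $\mathsf{C}$ by default
  — $\chi$ is defined about the reference, not about the ensemble mean.
  A `center = TRUE` option exists for drifted ensembles, at the price of
  breaking the identity by the mean's contribution).
- At least $d^2 = 9$ eigenvalues vanish: the affine subspace is
  annihilated by construction.
- The **gap** $\Gamma = 1 - \lambda_2/\lambda_1$ on the max-normalized
  spectrum measures how much a single soft non-affine mode dominates a
  site. We emit the absolute difference $\lambda_1 - \lambda_2$ too, but
  the normalized form is primary because it is dimensionless and
  comparable across sites with different overall mobility.
- The **NAP susceptibility** $\langle(\chi - \langle\chi\rangle)^2\rangle$
  (population $1/T$ convention throughout, matching the ensemble-average
  notation) flags sites whose non-affine fluctuations are large — in apo
  ensembles these correlate with where ligands bind.
- The residue–residue covariance
  $\langle(\chi_i - \langle\chi_i\rangle)(\chi_j -
  \langle\chi_j\rangle)\rangle$ is kept as a covariance (not a Pearson
  correlation) because the susceptibility scale is itself informative; a
  normalized map is available via `correlation_map(..., normalize =
  TRUE)`.

## Parameters that matter

**Neighborhood size.** $\Omega_i$ is radius-defined with the center
excluded and hydrogens excluded by default. Too few members make the
affine fit underdetermined and $\chi$ noisy; too many average away local
signal. The practical window is 50–100 heavy atoms;
`calibrate_radius()` scans a 0.1 Å grid for the smallest radius whose
median heavy-atom count lands in that window (about 5.5–6 Å at typical
protein interior density of 0.1 heavy atoms/Å³). A k-nearest option
exists and is what our graded-softness analyses use, because it holds the
non-affine dimension $3n_\Omega - 9$ fixed across sites — with
radius-defined neighborhoods the noise floors of both susceptibility and
gap vary with $n_\Omega$ and can scramble rankings among weakly
distinguished sites. A hard floor `min_size` (default 10) rejects
degenerate neighborhoods by error rather than silently.

**Conditioning.** $(\mathsf{R}^{\mathsf T}\mathsf{R})^{-1}$ is computed by
a direct solve after an SVD rank check; neighborhoods with
$\mathrm{cond}(\mathsf{R}^{\mathsf T}\mathsf{R}) > 10^8$ (near-planar or
near-collinear geometry) are refused by `build_projection` and excluded
from residue aggregates with an explicit NA marker and a warning — no
silent pseudo-inverse.

**Units and normalization.** Everything internal is Å (GRO input is
converted from nm on read); $\chi$ is reported in Å² as the unnormalized
neighborhood sum, which is what the trace identity and the closed-form
results below assume. Divide by $n_\Omega$ externally if cross-site
comparison at different neighborhood sizes is needed.

**Pair extraction.** "Spatially distant" for allosteric candidates is
operationalized as sequence separation ≥ 10 residues *and* reference
anchor (Cα, centroid fallback) distance ≥ 12 Å, both configurable —
bonded and contacting residues are trivially correlated and must be
excluded. The covariance threshold defaults to 4% of the *off-diagonal*
maximum: the diagonal holds the susceptibilities, which would otherwise
dominate the scale; thresholding on the full-matrix maximum is the
documented alternative and simply rescales `fraction`.

**Model index and reference choice.** The reference may be a crystal
model (default) or a time-averaged structure supplied via
`as_reference`; the choice is recorded in the object's `source` tag.
Because $\chi$ is invariant under global rotation + translation of the
frame (tested to $10^{-8}$), no superposition of the trajectory onto the
reference is required or applied.

## What the synthetic generators emulate

- `affine_ensemble`: a per-frame global deformation $\mathsf{D}_t$ —
  the null case. $\chi$ must vanish to round-off at every site
  (observed: $\lesssim 10^{-15}$ of the mean squared displacement).
- `mode_ensemble`: reference + $\sum_k a^{(k)}_t \hat e_k$ + isotropic
  Gaussian noise, with each planted $\hat e_k$ constructed *inside* the
  non-affine subspace of its site ($\mathsf{P}\hat e = \hat e$ by
  projection at construction, validated again at generation). Modes
  sharing a `group` share their amplitude draws $a_t$, which plants
  correlated distal sites for allosteric-recovery tests. Amplitudes are
  $N(0, \mathrm{amp}^2)$.
- `field_ensemble`: displacements drawn from the Gaussian with precision
  $\sigma^{-2}\mathsf{I} - 2h\mathsf{P}$, i.e. a field $h$ conjugate to
  $\chi$ itself. Stable only for $h < 1/(2\sigma^2)$ (enforced by
  error). Closed form: $\langle\chi\rangle(h) = (3n_\Omega - 9)\,
  \sigma^2/(1 - 2h\sigma^2)$, whence
  $\mathrm{d}\langle\chi\rangle/\mathrm{d}h|_0 = 2(3n_\Omega-9)\sigma^4
  = \langle(\chi-\langle\chi\rangle)^2\rangle_0$ — the
  fluctuation–response relation $\langle\chi\rangle = \langle\chi\rangle_0
  + h_\chi \langle(\chi-\langle\chi\rangle)^2\rangle_0$ that motivates
  reading ligands as local fields conjugate to non-affinity.
- `gaussian_deltas`: i.i.d. Gaussian displacement vectors, the
  random-matrix null whose $\mathsf{P C P}$ spectrum follows the
  Marchenko–Pastur law with $q = (3n_\Omega - 9)/T$.

What these do **not** emulate: bonded connectivity and excluded volume,
anisotropic and temporally correlated thermal noise, solvent damping,
and any real free-energy surface. Consequently, passing tests demonstrate
the *mathematical* claims (projection identities, spectral structure,
recovery power of the estimators at stated signal-to-noise) — they do
not certify hotspot predictions on real proteins, which additionally
depend on sampling quality and force-field fidelity of the input
ensemble.

One physical feature the generators *do* share with real data deserves
note: because $\boldsymbol{\Delta}_{ij}$ subtracts the center atom's
displacement, independent center noise induces a collective
"uniform-shift" component of variance $\sim n_\Omega\sigma^2$ in
$\boldsymbol{\Delta}$ that is largely non-affine. It forms the leading
edge of the noise spectrum, so planted-mode gaps saturate below 1 even at
high amplitude ratios. This is intrinsic to the relative-displacement
definition, not an artifact.

## Numerical choices

- Eigen-decompositions use the symmetric solver on the explicitly
  symmetrized $\mathsf{P C P}$; eigenvector signs are fixed
  (largest-magnitude component positive) and near-degenerate top pairs
  ($\lambda_1 - \lambda_2 < 10^{-2}\lambda_1$) are flagged so the
  "dominant mode" is never silently an arbitrary basis vector.
- Tiny negative $\chi$ from round-off is clamped to zero.
- The Marchenko–Pastur fit is moment-matched ($\sigma^2$ = mean non-zero
  eigenvalue, $q$ from dimensions), not maximum-likelihood: it is
  deterministic, parameter-free, and fully adequate for a visual/KS
  comparison. Its CDF is evaluated by trapezoidal quadrature on a
  4000-point grid over the support; for $q \ge 1$ the point mass at zero
  is included and a warning is raised. The KS statistic uses the standard
  two-sided empirical-CDF bound at the sorted eigenvalues.
- `mode_ensemble` draws all noise before all amplitudes, so the
  zero-amplitude limit is *bit-identical* to the no-mode isotropic
  ensemble under the same seed; all generators restore the caller's RNG
  state.
- The fluctuation–response check uses a central difference at $h = \pm
  0.04$ ($\sigma = 1$): the forward difference carries an $O(h)$ bias of
  $2h/(1-2h) \approx 9\%$, which would consume most of a 10% band for
  what is an exact identity; the central difference reduces the bias to
  $4h^2 \approx 0.6\%$. Negative $h$ is a perfectly valid stiffening
  field.

## Problem sizes

The test and acceptance runs use clouds of 300–1000 atoms, neighborhoods
of 12–60 members, ensembles of 50–600 frames (2500 for the
fluctuation–response estimate, whose variance estimator needs
$\sqrt{2/T}$ relative precision), 20 graded-softness clusters of 90 atoms,
and a 60-residue helical chain for residue-level pair recovery. These
sizes put every sampling-based assertion at least 3 standard errors from
its threshold while keeping the full suite under half a minute; the
estimators themselves are $O(T n_\Omega^2 d^2)$ per site and scale to
real trajectories unchanged.

## Known limitations

- Neighborhoods assume the whole molecule is given in one piece: no
  periodic-boundary minimum-image handling.
- The deformation matrix $\mathsf{D}$ is unconstrained; a pure-strain
  (symmetric) variant is not implemented.
- Same-time covariances only; no time-lagged correlation or kinetic
  modelling.
- Statistical significance of supra-threshold pairs is not assessed
  beyond the fixed-fraction threshold; on short ensembles the pair list
  should be read as a ranking, not a hypothesis test.
- mmCIF input and trajectory formats beyond PDB/DCD/GRO are out of
  scope.
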