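# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic reference structure
#'
#' Geometries:
#' \describe{
#'   \item{lattice}{simple cubic lattice, `side^3` atoms at `spacing`.}
#'   \item{cloud}{uniform cloud of `n_atoms` in a cube sized so the heavy
#'     atom density equals `density` (default 0.1 atoms/A^3, typical
#'     protein-interior heavy-atom packing).}
#'   \item{helix}{a helical chain of `n_atoms` (radius `helix_radius`,
#'     `rise` per atom), a spatially ordered stand-in for a polymer so
#'     sequence-distant residues are also spatially distant.}
#'   \item{clusters}{`n_clusters` uniform balls of `cluster_size` atoms at
#'     `density`, centers on a grid `cluster_sep` apart — disjoint analysis
#'     sites for graded-softness ensembles.}
#' }
#' All atoms are carbon (all heavy); atoms are grouped into pseudo-residues
#' of `residue_size` consecutive atoms to emulate residue-level protein
#' granularity.
#'
#' @param geometry one of "lattice", "cloud", "helix", "clusters".
#' @param n_atoms atom count (cloud/helix; lattice uses `side`).
#' @param side lattice side length in atoms (default 5).
#' @param spacing lattice spacing, Angstrom (default 1.5).
#' @param density heavy-atom density in atoms/A^3 (default 0.1).
#' @param helix_radius,rise helix geometry, Angstrom (defaults 2.5, 0.4).
#' @param n_clusters,cluster_size,cluster_sep clusters geometry.
#' @param residue_size atoms per pseudo-residue (default 8).
#' @param seed RNG seed (generation is bit-reproducible given the seed).
#' @return a [as_reference()] object; for "clusters", the attribute
#'   `cluster_centers` holds the index of each cluster's centermost atom.
#' @export
make_reference <- function(geometry = c("cloud", "lattice", "helix",
                                        "clusters"),
                           n_atoms = 500L, side = 5L, spacing = 1.5,
                           density = 0.1, helix_radius = 2.5, rise = 0.4,
                           n_clusters = 20L, cluster_size = 90L,
                           cluster_sep = 30, residue_size = 8L, seed = 1L) {
  geometry <- match.arg(geometry)
  centers <- NULL
  xyz <- switch(geometry,
    lattice = {
      g <- seq_len(side) * spacing
      as.matrix(expand.grid(x = g, y = g, z = g))
    },
    cloud = with_seed(seed, {
      L <- (n_atoms / density)^(1 / 3)
      matrix(stats::runif(3L * n_atoms, 0, L), ncol = 3L)
    }),
    helix = {
      i <- seq_len(n_atoms)
      ang <- i * 2 * pi / 11  # ~11 atoms per turn
      cbind(helix_radius * cos(ang), helix_radius * sin(ang), i * rise)
    },
    clusters = with_seed(seed, {
      r <- (3 * cluster_size / (4 * pi * density))^(1 / 3)
      ngrid <- ceiling(n_clusters^(1 / 3))
      grid <- as.matrix(expand.grid(x = seq_len(ngrid), y = seq_len(ngrid),
                                    z = seq_len(ngrid)))[seq_len(n_clusters), ,
                                                         drop = FALSE]
      grid <- grid * cluster_sep
      do.call(rbind, lapply(seq_len(n_clusters), function(k) {
        # uniform in a ball of radius r
        u <- matrix(stats::rnorm(3L * cluster_size), ncol = 3L)
        u <- u / sqrt(rowSums(u^2)) * r * stats::runif(cluster_size)^(1 / 3)
        sweep(u, 2L, grid[k, ], "+")
      }))
    })
  )
  n <- nrow(xyz)
  res <- (seq_len(n) - 1L) %/% residue_size + 1L
  ref <- as_reference(xyz,
                      element = rep("C", n),
                      atom_name = paste0("C", (seq_len(n) - 1L) %%
                                           residue_size + 1L),
                      resid = res, resname = rep("ALA", n),
                      chain = rep("A", n), source = "synthetic")
  if (geometry == "clusters") {
    r0 <- (3 * cluster_size / (4 * pi * density))^(1 / 3)
    centers <- vapply(seq_len(n_clusters), function(k) {
      idx <- (k - 1L) * cluster_size + seq_len(cluster_size)
      mid <- colMeans(ref$xyz[idx, , drop = FALSE])
      idx[which.min(colSums((t(ref$xyz[idx, , drop = FALSE]) - mid)^2))]
    }, numeric(1))
    attr(ref, "cluster_centers") <- centers
  }
  ref
}

#' Ensemble generated by a per-frame global affine deformation
#'
#' Frame t has positions \eqn{c + D_t (R - c)} with c the reference
#' centroid. Every local displacement field in such an ensemble is exactly
#' affine, so chi vanishes at every site and frame (up to round-off).
#'
#' @param ref a [as_reference()] object.
#' @param D_t a function `t -> 3x3 matrix`, or a list of 3x3 matrices.
#' @param T number of frames.
#' @return a [as_ensemble()] object.
#' @export
affine_ensemble <- function(ref, D_t, T) {
  ctr <- colMeans(ref$xyz)
  rel <- sweep(ref$xyz, 2L, ctr)
  frames <- array(0, dim = c(T, ref$natoms, 3L))
  for (t in seq_len(T)) {
    D <- if (is.function(D_t)) D_t(t) else D_t[[t]]
    if (abs(det(D)) < 1e-12) stop("D_t must be invertible at t = ", t)
    frames[t, , ] <- sweep(rel %*% t(D), 2L, ctr, "+")
  }
  as_ensemble(frames)
}

#' Rotation matrix about a coordinate axis
#' @param angle angle in degrees.
#' @param axis 1, 2 or 3.
#' @export
rotation_matrix <- function(angle, axis = 3L) {
  a <- angle * pi / 180
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- cos(a); R[ij[2], ij[2]] <- cos(a)
  R[ij[1], ij[2]] <- -sin(a); R[ij[2], ij[1]] <- sin(a)
  R
}

#' Construct a planted mode in the non-affine subspace of a neighborhood
#'
#' Projects a random displacement field over the neighborhood members with
#' P and normalizes, guaranteeing \eqn{P e = e} so the mode is invisible to
#' the affine fit and fully visible to chi.
#'
#' @param nb a [build_neighborhood()] object.
#' @param amp amplitude standard deviation (Angstrom).
#' @param group modes sharing a `group` label share their per-frame
#'   amplitude draw a_t (used to plant correlated distal sites).
#' @param seed RNG seed.
#' @param P optional precomputed projection operator.
#' @return a `nap_mode`: list with `nb`, `field` (n x 3, unit norm,
#'   `P field = field`), `amp`, `group`.
#' @export
planted_mode <- function(nb, amp = 1, group = NULL, seed = 1L, P = NULL) {
  if (amp < 0) stop("amp must be non-negative")
  if (is.null(P)) P <- build_projection(nb)
  e <- with_seed(seed, stats::rnorm(3L * nb$n))
  e <- drop(P %*% e)
  e <- e / sqrt(sum(e^2))
  if (max(abs(drop(P %*% e) - e)) > 1e-10) {
    stop("constructed mode is not in the non-affine subspace")
  }
  m <- list(nb = nb, field = matrix(e, ncol = 3L, byrow = TRUE),
            amp = amp, group = group)
  class(m) <- "nap_mode"
  m
}

#' Ensemble with planted non-affine soft modes plus isotropic noise
#'
#' Frame t adds, on each mode's member atoms, `amp * a_t` times its unit
#' non-affine field (amplitudes \eqn{a_t \sim N(0,1)}, drawn independently
#' per mode unless modes share a `group`), plus i.i.d. isotropic
#' displacement noise \eqn{N(0, noise\_sigma^2)} on every atom. This is the
#' workhorse for gap/mode-recovery and graded-softness tests.
#'
#' @param ref a [as_reference()] object.
#' @param modes list of [planted_mode()] objects (may be empty).
#' @param noise_sigma isotropic noise standard deviation (Angstrom).
#' @param T number of frames.
#' @param seed RNG seed.
#' @return a [as_ensemble()] object; attribute `amplitudes` holds the
#'   T x n_modes matrix of realized `amp * a_t`.
#' @export
mode_ensemble <- function(ref, modes = list(), noise_sigma = 0.1, T = 100L,
                          seed = 1L) {
  for (m in modes) {
    if (!inherits(m, "nap_mode")) stop("modes must be planted_mode objects")
    P <- build_projection(m$nb)
    e <- as.vector(t(m$field))
    if (max(abs(drop(P %*% e) - e)) > 1e-8) {
      stop("planted mode at atom ", m$nb$center,
           " is not in the non-affine subspace")
    }
  }
  groups <- vapply(seq_along(modes), function(k) {
    g <- modes[[k]]$group
    if (is.null(g)) paste0(".mode", k) else as.character(g)
  }, character(1))
  ug <- unique(groups)
  with_seed(seed, {
    # noise drawn before amplitudes so the zero-amplitude limit reproduces
    # the no-mode isotropic ensemble exactly
    frames <- array(0, dim = c(T, ref$natoms, 3L))
    for (t in seq_len(T)) {
      frames[t, , ] <- ref$xyz +
        matrix(stats::rnorm(3L * ref$natoms, 0, noise_sigma), ncol = 3L)
    }
    a_g <- matrix(stats::rnorm(T * length(ug)), T, length(ug),
                  dimnames = list(NULL, ug))
    amps <- matrix(0, T, length(modes))
    for (k in seq_along(modes)) {
      m <- modes[[k]]
      amps[, k] <- m$amp * a_g[, groups[k]]
      for (t in seq_len(T)) {
        frames[t, m$nb$members, ] <- frames[t, m$nb$members, ] +
          amps[t, k] * m$field
      }
    }
    structure(as_ensemble(frames), amplitudes = amps)
  })
}

#' Critical conjugate-field strength for a field ensemble
#'
#' The Gaussian with energy \eqn{\frac{1}{2\sigma^2}\|\Delta\|^2 - h
#' \Delta^T P \Delta} is normalizable only for \eqn{h < 1/(2\sigma^2)}.
#' @param sigma base displacement scale (Angstrom).
#' @export
field_h_max <- function(sigma) 1 / (2 * sigma^2)

#' Ensemble sampled under a conjugate non-affine field
#'
#' Samples the neighborhood displacement vector from the Gaussian whose
#' energy couples a field h to chi itself: precision \eqn{\sigma^{-2} I -
#' 2 h P}. Along the \eqn{n_\Omega d - d^2} non-affine directions the
#' variance is inflated (h > 0, ligand-like softening) or deflated (h < 0)
#' to \eqn{\sigma^2 / (1 - 2 h \sigma^2)}; affine directions keep variance
#' \eqn{\sigma^2}. Frames place the center at its reference position and
#' the members at reference + sampled displacement; atoms outside the
#' neighborhood stay at the reference. The expected chi has the closed form
#' returned by [chi_field_expected()].
#'
#' @param ref a [as_reference()] object.
#' @param nb a [build_neighborhood()] object.
#' @param h conjugate-field strength (1/Angstrom^2); must satisfy
#'   `h < field_h_max(sigma)`.
#' @param sigma base displacement standard deviation (Angstrom).
#' @param T number of frames.
#' @param seed RNG seed.
#' @return a [as_ensemble()] object.
#' @export
field_ensemble <- function(ref, nb, h, sigma = 1, T = 500L, seed = 1L) {
  hmax <- field_h_max(sigma)
  if (h >= hmax) {
    stop("field h = ", h, " at or above the stability bound 1/(2 sigma^2) = ",
         format(hmax, digits = 4))
  }
  P <- build_projection(nb)
  s_na <- sigma / sqrt(1 - 2 * h * sigma^2)
  with_seed(seed, {
    frames <- array(0, dim = c(T, ref$natoms, 3L))
    for (t in seq_len(T)) {
      z <- stats::rnorm(3L * nb$n)
      pz <- drop(P %*% z)
      delta <- sigma * (z - pz) + s_na * pz
      fr <- ref$xyz
      fr[nb$members, ] <- fr[nb$members, ] +
        matrix(delta, ncol = 3L, byrow = TRUE)
      frames[t, , ] <- fr
    }
    as_ensemble(frames)
  })
}

#' Closed-form ensemble-average chi under a conjugate field
#'
#' \eqn{\langle\chi\rangle(h) = (n_\Omega d - d^2) \sigma^2 / (1 - 2 h
#' \sigma^2)}: each non-affine direction contributes its inflated variance.
#' @param nb a [build_neighborhood()] object.
#' @param h field strength; `h = 0` gives the zero-field baseline.
#' @param sigma base displacement standard deviation.
#' @export
chi_field_expected <- function(nb, h, sigma = 1) {
  (3L * nb$n - 9L) * sigma^2 / (1 - 2 * h * sigma^2)
}

#' I.i.d. Gaussian displacement vectors (random-matrix null)
#'
#' Draws T displacement vectors with i.i.d. N(0, sigma^2) components —
#' the truly random ensemble whose projected correlator spectrum follows
#' the Marchenko-Pastur law.
#'
#' @param dim stacked dimension (3 n_Omega).
#' @param T number of frames.
#' @param sigma component standard deviation (default 1).
#' @param seed RNG seed.
#' @return dim x T matrix.
#' @export
gaussian_deltas <- function(dim, T, sigma = 1, seed = 1L) {
  with_seed(seed, matrix(stats::rnorm(dim * T, 0, sigma), dim, T))
}
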