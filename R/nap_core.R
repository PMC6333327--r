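#' Stacked relative displacements for one frame and one neighborhood
#'
#' With atomic displacements \eqn{u_i = r_i - R_i}, the displacement of
#' member j relative to the center i is \eqn{\Delta_{ij} = u_j - u_i}. The
#' members' \eqn{\Delta_{ij}} are stacked (x,y,z contiguous per member, in
#' the neighborhood's member order) into one \eqn{n_\Omega d}-vector.
#'
#' Global translations cancel exactly in \eqn{\Delta_{ij}}; global rotations
#' do not, but are affine and hence removed later by the projection.
#'
#' @param ref a [as_reference()] object.
#' @param frame N x 3 coordinate matrix with the reference's atom order
#'   (see [frame_coords()]).
#' @param nb a [build_neighborhood()] object.
#' @return numeric vector of length `3 * nb$n`.
#' @export
displacements <- function(ref, frame, nb) {
  u <- frame - ref$xyz
  du <- sweep(u[nb$members, , drop = FALSE], 2L, u[nb$center, ])
  as.vector(t(du))
}

# Delta vectors for all frames at once: (3 n_Omega) x T matrix.
delta_matrix <- function(ref, ens, nb) {
  Tn <- ens$nframes
  out <- matrix(0, 3L * nb$n, Tn)
  for (t in seq_len(Tn)) {
    out[, t] <- displacements(ref, frame_coords(ens, t), nb)
  }
  out
}

#' Projection operator onto the non-affine subspace
#'
#' \eqn{P = I - R (R^T R)^{-1} R^T} annihilates every displacement field of
#' the form \eqn{\Delta_{ij} = D (R_j - R_i)} for any 3x3 matrix D
#' (rotations, strains, shears), leaving only the non-affine component.
#' P is a symmetric orthogonal projector of rank \eqn{n_\Omega d - d^2}.
#'
#' Neighborhoods whose \eqn{R^T R} has condition number above `max_cond`
#' are rejected: the affine fit there is numerically unreliable.
#'
#' @param nb a [build_neighborhood()] object.
#' @param max_cond condition-number threshold for \eqn{R^T R} (default 1e8).
#' @return a `nap_projection`: the (3n) x (3n) matrix `P` with attributes
#'   `rank` and `cond`.
#' @export
build_projection <- function(nb, max_cond = 1e8) {
  if (nb$cond > max_cond) {
    stop("ill-conditioned neighborhood at atom ", nb$center,
         ": cond(R^T R) = ", format(nb$cond, digits = 3),
         " exceeds ", max_cond)
  }
  R <- nb$R
  m <- nrow(R)
  P <- diag(m) - R %*% solve(crossprod(R), t(R))
  P <- (P + t(P)) / 2
  structure(P, class = c("nap_projection", "matrix"),
            rank = m - 9L, cond = nb$cond)
}

#' Non-affine parameter by projection
#'
#' \eqn{\chi = \Delta^T P \Delta} (Angstrom^2): the squared norm of the
#' non-affine component of the local displacement field. Tiny negative
#' round-off is clamped to zero.
#'
#' @param delta a [displacements()] vector.
#' @param P a [build_projection()] operator.
#' @return non-negative scalar chi.
#' @export
chi_projected <- function(delta, P) {
  if (length(delta) != nrow(P)) {
    stop("dimension mismatch: delta has length ", length(delta),
         ", P is ", nrow(P), " x ", ncol(P))
  }
  chi <- drop(crossprod(delta, P %*% delta))
  if (chi < 0) chi <- 0
  chi
}

#' Non-affine parameter by explicit least-squares affine fit
#'
#' Solves \eqn{\min_D \sum_j \| \Delta_{ij} - D (R_j - R_i) \|^2} through
#' the normal equations \eqn{(R^T R) vec(D) = R^T \Delta} and returns the
#' best deformation matrix D and the residual, which equals chi. This is
#' the definitional route; [chi_projected()] is the equivalent projection
#' route, and the two agree to round-off.
#'
#' @param delta a [displacements()] vector.
#' @param nb a [build_neighborhood()] object.
#' @return list with `D` (3 x 3 best affine deformation) and `residual`
#'   (chi, Angstrom^2).
#' @export
chi_direct <- function(delta, nb) {
  R <- nb$R
  if (length(delta) != nrow(R)) {
    stop("dimension mismatch: delta has length ", length(delta),
         ", R has ", nrow(R), " rows")
  }
  vecD <- solve(crossprod(R), crossprod(R, delta))
  resid <- sum((delta - R %*% vecD)^2)
  list(D = matrix(vecD, 3L, 3L, byrow = TRUE), residual = resid)
}

#' Per-frame chi series for one neighborhood
#'
#' Evaluates \eqn{\chi_t = \Delta_t^T P \Delta_t} for every frame, reusing
#' one cached projection operator (P depends only on the reference).
#'
#' @param ref a [as_reference()] object.
#' @param ens a [as_ensemble()] object.
#' @param nb a [build_neighborhood()] object.
#' @param P optional precomputed [build_projection()] operator.
#' @return numeric vector of length `ens$nframes` (Angstrom^2).
#' @export
chi_series <- function(ref, ens, nb, P = NULL) {
  if (is.null(P)) P <- build_projection(nb)
  vapply(seq_len(ens$nframes), function(t) {
    chi_projected(displacements(ref, frame_coords(ens, t), nb), P)
  }, numeric(1))
}
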