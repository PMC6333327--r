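#' Build the coarse-graining neighborhood of an atom
#'
#' The non-affine parameter is defined over a fixed neighborhood
#' \eqn{\Omega_i} around each analysed atom i. Members are the atoms (by
#' default heavy atoms only) within `radius` of the center in the reference
#' geometry, excluding the center itself; alternatively the `k` nearest
#' atoms. A practical neighborhood for protein work holds 50-100 heavy
#' atoms; see [calibrate_radius()].
#'
#' The reference-geometry matrix R has dimension \eqn{(n_\Omega d) \times
#' d^2} (d = 3) with entries \eqn{R_{j\alpha,\gamma\gamma'} =
#' \delta_{\alpha\gamma} (R_j - R_i)_{\gamma'}}, i.e. the block for member j
#' maps a 3x3 deformation matrix D (stored row-major in a 9-vector) to
#' \eqn{D (R_j - R_i)}.
#'
#' @param ref a [as_reference()] object.
#' @param center 1-based atom index of the neighborhood center.
#' @param radius cutoff in Angstrom (used unless `k` is given).
#' @param k optional number of nearest neighbors (k-nearest mode).
#' @param heavy_only exclude hydrogens (default TRUE).
#' @param min_size minimum admissible \eqn{n_\Omega} (default 10).
#' @return An object of class `nap_neighborhood`: list with `center`,
#'   `members` (ascending atom indices, center excluded), `radius`, `rel`
#'   (n x 3 member positions relative to the center), `R` (the geometry
#'   matrix), `n` (\eqn{n_\Omega}) and `cond` (condition number of
#'   \eqn{R^T R}).
#' @export
build_neighborhood <- function(ref, center, radius = NULL, k = NULL,
                               heavy_only = TRUE, min_size = 10L) {
  if (center < 1L || center > ref$natoms) stop("invalid center index")
  cand <- seq_len(ref$natoms)
  if (heavy_only) cand <- cand[ref$heavy[cand]]
  cand <- setdiff(cand, center)
  d2 <- colSums((t(ref$xyz[cand, , drop = FALSE]) - ref$xyz[center, ])^2)
  if (!is.null(k)) {
    if (k > length(cand)) stop("k = ", k, " exceeds available atoms")
    members <- cand[order(d2)[seq_len(k)]]
    radius <- sqrt(max(d2[match(members, cand)]))
  } else {
    if (is.null(radius) || radius <= 0) stop("radius must be positive")
    members <- cand[d2 <= radius^2]
  }
  members <- sort(members)
  n <- length(members)
  if (n < min_size) {
    stop("degenerate neighborhood at atom ", center, ": only ", n,
         " member(s), minimum is ", min_size)
  }
  rel <- sweep(ref$xyz[members, , drop = FALSE], 2L, ref$xyz[center, ])
  R <- r_matrix(rel)
  RtR <- crossprod(R)
  sv <- svd(RtR, nu = 0, nv = 0)$d
  if (sum(sv > max(sv) * 1e-12) < 9L) {
    stop("collinear neighborhood at atom ", center,
         ": rank(R^T R) < 9")
  }
  nb <- list(center = center, members = members, radius = radius,
             rel = rel, R = R, n = n, cond = sv[1] / sv[9])
  class(nb) <- "nap_neighborhood"
  nb
}

#' @export
print.nap_neighborhood <- function(x, ...) {
  cat("nap_neighborhood: center atom", x$center, "| n_Omega =", x$n,
      "| radius =", round(x$radius, 2), "A | cond(RtR) =",
      format(x$cond, digits = 3), "\n")
  invisible(x)
}

#' Reference-geometry matrix R from relative member positions
#'
#' @param rel n x 3 matrix of member positions relative to the center.
#' @return the (3n) x 9 matrix with block rows
#'   \eqn{\delta_{\alpha\gamma} b_{j\gamma'}}, row-major D convention.
#' @export
r_matrix <- function(rel) {
  n <- nrow(rel)
  R <- matrix(0, 3L * n, 9L)
  for (a in 1:3) {
    R[seq.int(a, 3L * n, by = 3L), (a - 1L) * 3L + (1:3)] <- rel
  }
  R
}

#' Calibrate the neighborhood radius to a target atom-count window
#'
#' Scans radii on a 0.1 Angstrom grid and returns the smallest radius whose
#' median heavy-atom neighborhood size (over all heavy-atom centers) falls
#' inside `target` — by default the 50-100 heavy-atom window appropriate
#' for protein coarse-graining.
#'
#' @param ref a [as_reference()] object.
#' @param target length-2 integer vector, inclusive count window.
#' @param grid radius grid spacing in Angstrom (default 0.1).
#' @return radius in Angstrom.
#' @export
calibrate_radius <- function(ref, target = c(50L, 100L), grid = 0.1) {
  if (length(target) != 2L || target[1] > target[2]) {
    stop("target must be a non-empty count range")
  }
  idx <- which(ref$heavy)
  nh <- length(idx)
  if (nh - 1L < target[1]) {
    stop("unreachable target: only ", nh, " heavy atoms, need median >= ",
         target[1], " neighbors")
  }
  D <- as.matrix(stats::dist(ref$xyz[idx, , drop = FALSE]))
  rmax <- max(D)
  for (r in seq(grid, rmax + grid, by = grid)) {
    med <- stats::median(colSums(D <= r) - 1L)
    if (med >= target[1] && med <= target[2]) return(r)
    if (med > target[2]) break
  }
  stop("no radius on the ", grid,
       " A grid reaches a median count in [", target[1], ", ",
       target[2], "]")
}
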