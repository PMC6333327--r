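#' Local displacement correlator
#'
#' \eqn{C = \langle \Delta \Delta^T \rangle}: the (3n) x (3n) second-moment
#' matrix of the stacked relative displacements over frames. By default no
#' mean is subtracted — chi itself is defined about the fixed reference, and
#' keeping the raw second moment makes the trace identity
#' \eqn{\langle\chi\rangle = \sum_\mu \lambda_\mu} exact. Set
#' `center = TRUE` for drifted ensembles.
#'
#' @param deltas (3n) x T matrix of per-frame displacement vectors
#'   (see [displacements()]), or a list of such vectors.
#' @param center subtract the mean displacement first (default FALSE).
#' @return a `nap_correlator`: symmetric PSD matrix with attribute
#'   `n_frames`.
#' @export
correlator <- function(deltas, center = FALSE) {
  if (is.list(deltas)) deltas <- do.call(cbind, deltas)
  Tn <- ncol(deltas)
  if (Tn < 2L) stop("correlator needs at least 2 frames, got ", Tn)
  if (center) deltas <- deltas - rowMeans(deltas)
  C <- tcrossprod(deltas) / Tn
  C <- (C + t(C)) / 2
  structure(C, class = c("nap_correlator", "matrix"), n_frames = Tn)
}

#' Eigen-spectrum of the projected correlator PCP
#'
#' Diagonalizes \eqn{P C P}. Its eigenvalues \eqn{\lambda_\mu} sum to the
#' ensemble-average non-affine parameter; at least \eqn{d^2 = 9} of them
#' vanish (the affine subspace is annihilated). The spectrum is reported
#' both raw (Angstrom^2) and normalized by the largest eigenvalue, and the
#' spectral gap \eqn{\Gamma = 1 - \lambda_2/\lambda_1} on the normalized
#' scale measures how strongly a single soft non-affine mode dominates the
#' site. Eigenvector signs are fixed (largest-magnitude component positive)
#' for reproducibility.
#'
#' @param P a [build_projection()] operator.
#' @param C a [correlator()] matrix.
#' @param zero_tol eigenvalues below `zero_tol * lambda_1` count as zero.
#' @return a `nap_spectrum`: list with `values` (descending), `vectors`
#'   (columns), `normalized`, `gap` (\eqn{1-\lambda_2/\lambda_1}),
#'   `gap_abs` (\eqn{\lambda_1-\lambda_2}, Angstrom^2), `n_zero`,
#'   `n_frames`.
#' @export
pcp_spectrum <- function(P, C, zero_tol = 1e-10) {
  if (!isTRUE(all.equal(dim(P), dim(C)))) {
    stop("dimension mismatch between P and C")
  }
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    stop("correlator is not symmetric")
  }
  M <- P %*% C %*% P
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  val <- eg$values
  val[val < 0 & val > -1e-10 * max(abs(val), 1)] <- 0
  vec <- eg$vectors
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  l1 <- val[1]
  norm <- if (l1 > 0) val / l1 else val
  gap <- if (l1 > 0) 1 - val[2] / l1 else 0
  sp <- list(values = val, vectors = vec, normalized = norm,
             gap = gap, gap_abs = val[1] - val[2],
             n_zero = sum(val < zero_tol * max(l1, zero_tol)),
             n_frames = attr(C, "n_frames"))
  class(sp) <- "nap_spectrum"
  sp
}

#' @export
print.nap_spectrum <- function(x, ...) {
  cat("nap_spectrum:", length(x$values), "eigenvalues | lambda_1 =",
      format(x$values[1], digits = 4), "A^2 | gap Gamma =",
      round(x$gap, 3), "|", x$n_zero, "zero modes\n")
  invisible(x)
}

#' Dominant non-affine mode as a per-member displacement field
#'
#' Unstacks the top eigenvector of PCP to an \eqn{n_\Omega \times 3}
#' displacement field over the neighborhood members. When the top two
#' eigenvalues are nearly degenerate the returned mode is an arbitrary
#' rotation within the top eigenspace; a warning is issued and recorded in
#' the `degenerate` attribute.
#'
#' @param spec a [pcp_spectrum()] object.
#' @param nb the [build_neighborhood()] the spectrum belongs to.
#' @param tol degeneracy threshold on \eqn{(\lambda_1-\lambda_2)/\lambda_1}.
#' @return n x 3 matrix (unit Frobenius norm) with attributes `members`,
#'   `eigenvalue`, `degenerate`.
#' @export
dominant_mode <- function(spec, nb, tol = 1e-2) {
  if (spec$values[1] <= 0) stop("no positive eigenvalue: spectrum is empty")
  degen <- (spec$values[1] - spec$values[2]) < tol * spec$values[1]
  if (degen) {
    warning("top eigenvalue pair nearly degenerate at atom ", nb$center,
            ": dominant mode is defined only up to rotation")
  }
  v <- spec$vectors[, 1]
  mode <- matrix(v, ncol = 3L, byrow = TRUE)
  structure(mode, members = nb$members, eigenvalue = spec$values[1],
            degenerate = degen)
}

#' Overlap between two displacement-field modes
#'
#' Absolute inner product after normalization; 1 means identical up to sign.
#' @param a,b n x 3 mode matrices (or 3n vectors) over the same members.
#' @export
mode_overlap <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# Marchenko-Pastur CDF at points x for scale sigma2 and aspect ratio q,
# by trapezoidal integration of the density on the support.
mp_cdf <- function(x, sigma2, q, npts = 4000L) {
  lm <- sigma2 * (1 - sqrt(q))^2
  lp <- sigma2 * (1 + sqrt(q))^2
  grid <- seq(lm, lp, length.out = npts)
  dens <- suppressWarnings(
    sqrt(pmax((lp - grid) * (grid - lm), 0)) / (2 * pi * sigma2 * q * grid))
  dens[!is.finite(dens)] <- 0
  dx <- grid[2] - grid[1]
  cum <- c(0, cumsum((dens[-1] + dens[-npts]) / 2 * dx))
  cum <- cum / cum[npts]  # normalize residual quadrature error
  pm <- if (q > 1) 1 - 1 / q else 0  # point mass at zero when q > 1
  out <- stats::approx(grid, cum, xout = x, yleft = 0, yright = 1,
                       rule = 2)$y
  pm + (1 - pm) * out
}

#' Moment-matched Marchenko-Pastur fit of the non-zero PCP spectrum
#'
#' Fits the random-matrix null: a sample covariance of i.i.d. displacement
#' vectors of dimension m observed over T frames has eigenvalues following
#' the Marchenko-Pastur law with aspect ratio \eqn{q = m/T} and scale
#' \eqn{\sigma^2}. Here m is the non-affine dimension
#' \eqn{n_\Omega d - d^2}, \eqn{\sigma^2} is moment-matched as the mean
#' non-zero eigenvalue, and the fit quality is the Kolmogorov-Smirnov
#' distance between the empirical non-zero eigenvalue CDF and the fitted MP
#' CDF. Eigenvalues outside the MP support \eqn{\sigma^2 (1 \pm
#' \sqrt{q})^2} are flagged: such outliers carry structure the random null
#' cannot explain (the soft non-affine modes of active sites).
#'
#' @param spec a [pcp_spectrum()] object.
#' @param n_frames number of frames used to build the correlator; defaults
#'   to the count recorded in the spectrum.
#' @return a `nap_mpfit`: list with `sigma2`, `q`, `lambda_minus`,
#'   `lambda_plus`, `ks_stat`, `outliers` (indices into the sorted
#'   spectrum), `n_used`.
#' @export
mp_fit <- function(spec, n_frames = spec$n_frames) {
  if (is.null(n_frames)) stop("n_frames is required")
  m <- length(spec$values) - 9L  # non-affine dimension
  nz <- spec$values[seq_len(m)]
  nz <- nz[nz > 0]
  if (length(nz) < 10L) stop("need at least 10 non-zero eigenvalues, got ",
                             length(nz))
  q <- m / n_frames
  if (q >= 1) {
    warning("q = m/T = ", format(q, digits = 3),
            " >= 1: MP law has a point mass at zero; fit is indicative only")
  }
  sigma2 <- mean(nz)
  lm <- sigma2 * (1 - sqrt(q))^2
  lp <- sigma2 * (1 + sqrt(q))^2
  xs <- sort(nz)
  Fmp <- mp_cdf(xs, sigma2, q)
  n <- length(xs)
  ks <- max(abs(seq_len(n) / n - Fmp), abs((seq_len(n) - 1) / n - Fmp))
  out <- which(spec$values[seq_len(m)] > lp | (spec$values[seq_len(m)] < lm &
                                              spec$values[seq_len(m)] > 0))
  fit <- list(sigma2 = sigma2, q = q, lambda_minus = lm, lambda_plus = lp,
              ks_stat = ks, outliers = out, n_used = n)
  class(fit) <- "nap_mpfit"
  fit
}

#' @export
print.nap_mpfit <- function(x, ...) {
  cat("nap_mpfit: sigma2 =", format(x$sigma2, digits = 4), "| q =",
      format(x$q, digits = 3), "| support [",
      format(x$lambda_minus, digits = 3), ",",
      format(x$lambda_plus, digits = 3), "] | KS =",
      round(x$ks_stat, 4), "|", length(x$outliers), "outlier(s)\n")
  invisible(x)
}
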